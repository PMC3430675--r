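test_that("enrichment scores sum weights over enriching transitions", {
  w <- scoringWeights(3)  # 1, 2, 4
  expect_equal(enrichmentScore(c(10, 20, 40, 80), w), 7)
  expect_equal(enrichmentScore(c(10, 20, 15, 80), w), 5)
  expect_error(enrichmentScore(c(10, 20), w), "transition")

  # brute-force transition-count oracle on random frequency vectors
  for (seed in 1:200) {
    f <- withr::with_seed(seed, sample(0:50, 4, replace = TRUE))
    expected <- 0
    for (t in 1:3) if (f[t + 1] > f[t]) expected <- expected + w@w[t]
    expect_equal(enrichmentScore(f, w), expected)
  }
})

test_that("scores are scale-invariant and monotone in enriching transitions", {
  w <- scoringWeights(3)
  f <- c(10, 20, 15, 80)
  expect_equal(enrichmentScore(f * 37.5, w), enrichmentScore(f, w))
  # turning the failing middle transition into enrichment raises the score
  expect_gt(enrichmentScore(c(10, 20, 25, 80), w), enrichmentScore(f, w))
})

test_that("class labels rank distinct achieved scores", {
  expect_equal(assignClasses(c(7, 7, 5, 1)), c(1L, 1L, 2L, 3L))
  expect_equal(assignClasses(rep(1, 5)), rep(1L, 5))
  expect_length(assignClasses(numeric(0)), 0)

  # oracle: class = 1 + number of distinct scores strictly greater
  for (seed in 1:20) {
    s <- withr::with_seed(seed, sample(0:7, 12, replace = TRUE))
    expected <- vapply(s, function(v) 1L + sum(unique(s) > v), integer(1))
    expect_equal(assignClasses(s), expected)
  }
})

test_that("area fractions normalize to one", {
  expect_equal(areaFractions(300), 1)
  expect_equal(areaFractions(c(300, 100)), c(0.75, 0.25))
  fr <- withr::with_seed(2, areaFractions(runif(10, 1, 100)))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_error(areaFractions(numeric(0)), "positive")
})

test_that("central-99% width covers flat footprints exactly", {
  # the whole-bp range containing the central 99% of a flat footprint is
  # the footprint itself (up to 199 bp)
  expect_equal(peakWidth99(rep(1, 100)), 100L)
  for (f in c(35L, 50L, 80L, 190L)) expect_equal(peakWidth99(rep(3, f)), f)
  # a point mass spans one position
  expect_equal(peakWidth99(c(0, 50, 0)), 1L)
  expect_error(peakWidth99(numeric(10)), "positive mass")
})

test_that("central-99% width of a dense Gaussian is ~5.15 sigma", {
  sigma <- 60
  x <- exp(-((1:1000) - 500)^2 / (2 * sigma^2))
  expect_equal(peakWidth99(x), 2 * qnorm(0.995) * sigma, tolerance = 0.01)
})

test_that("binding-site length prediction inverts the footprint relation", {
  p <- predictBindingLength(172, 100)
  expect_equal(p$length, 28)
  expect_false(p$indeterminate)

  p <- predictBindingLength(200, 100)  # W = 2L: boundary
  expect_equal(p$length, 0)
  expect_true(p$indeterminate)
})

test_that("fragment-union footprints recover the planted site length exactly", {
  # Coverage as the union of all L-bp fragments containing a b-bp site is a
  # flat footprint of width 2L - b; the predictor must return b exactly.
  for (L in c(30L, 50L, 100L)) {
    for (b in seq(10L, L - 5L)) {
      s <- 300L  # site start; genome comfortably larger
      covered <- rep(FALSE, 800L)
      for (f in (s - (L - b)):s) covered[f:(f + L - 1L)] <- TRUE
      expect_equal(sum(covered), 2L * L - b)
      W <- peakWidth99(as.numeric(covered[min(which(covered)):max(which(covered))]))
      got <- predictBindingLength(W, L)
      expect_equal(got$length, b)
    }
  }
})

test_that("peak sequences are centered, clipped and uppercase", {
  g <- randomGenome(200, seed = 9)
  # apex 100, range 11: positions 95..105
  expect_equal(peakSequence(g, 100L, 11L), substr(g, 95, 105))
  # near the start the window truncates: apex 3, range 11 -> positions 1..8
  expect_equal(peakSequence(g, 3L, 11L), substr(g, 1, 8))
  expect_equal(nchar(peakSequence(g, 3L, 11L)), 8L)
  expect_equal(peakSequence("acgtacgtacgt", 6L, 3L), "ACG")

  # slice oracle on random apexes
  for (apex in withr::with_seed(3, sample(10:190, 20))) {
    expect_equal(peakSequence(g, apex, 15L),
                 substr(g, apex - 7L, apex + 7L))
  }
})

test_that("graded reports are hierarchical and fully annotated", {
  tri <- makeTriangleSeries()
  cfg <- peakCallConfig(20L, statRange = 100L, minApex = 5)
  peaks <- callPeaks(tri$series, cfg)
  genome <- randomGenome(2000, seed = 4)
  graded <- gradePeaks(peaks, tri$series, genome = genome, seqRange = 21L)

  expect_equal(nrow(graded), length(tri$apexes))
  # every planted peak enriches in every transition: all best class
  expect_equal(graded$class, rep(1L, 3))
  expect_equal(graded$score, rep(7, 3))
  # report order: within class, larger area first
  expect_equal(graded$area, sort(graded$area, decreasing = TRUE))
  expect_equal(graded$rank, 1:3)
  expect_equal(sum(graded$areaFraction), 1, tolerance = 1e-12)
  expect_true(all(graded$width99 <= graded$right - graded$left + 1))
  expect_equal(graded$sequence,
               peakSequence(genome, graded$apex, 21L))
  # frequencies at the apex, per cycle, control first
  expect_equal(graded$freq.cycle1,
               trackCounts(tri$series, 1)[graded$apex])
  expect_equal(graded$freq.cycle4,
               trackCounts(tri$series, 4)[graded$apex])
})

test_that("grading an empty peak set yields an empty report without error", {
  tri <- makeTriangleSeries()
  empty <- callPeaks(CycleSeries(list(
    FrequencyTrack(rep(5, 500), 1L), FrequencyTrack(rep(5, 500), 2L)), 20L),
    peakCallConfig(20L, statRange = 100L))
  graded <- gradePeaks(empty,
                       CycleSeries(list(FrequencyTrack(rep(5, 500), 1L),
                                        FrequencyTrack(rep(5, 500), 2L)), 20L),
                       weights = scoringWeights(1))
  expect_equal(nrow(graded), 0L)
  expect_true(all(c("rank", "class", "score", "predictedLength") %in%
                  names(graded)))
})

test_that("dropping later cycles weakly inflates the best class", {
  # Three peaks with staggered enrichment: all enrich early, fewer late.
  G <- 2000L; L <- 20L
  apexes <- c(300L, 900L, 1500L)
  bump <- function(track, apex, h) {
    x <- (apex - L):(apex + L)
    track[x] <- track[x] + h * (1 - abs(x - apex) / (L + 1))
    track
  }
  mkTrack <- function(heights, cycle) {
    tr <- numeric(G)
    for (i in 1:3) tr <- bump(tr, apexes[i], heights[i])
    FrequencyTrack(tr, cycle)
  }
  control <- FrequencyTrack(rep(1, G), 1L)
  trks <- list(control,
               mkTrack(c(50, 50, 50), 2L),     # all enrich
               mkTrack(c(100, 100, 50), 3L),   # first two enrich
               mkTrack(c(200, 100, 50), 4L))   # only the first enriches
  fracBest <- vapply(2:4, function(k) {
    series <- CycleSeries(trks[1:k], L)
    peaks <- callPeaks(series, peakCallConfig(L, statRange = 100L, minApex = 5))
    graded <- gradePeaks(peaks, series, weights = scoringWeights(k - 1L))
    mean(graded$class == 1L)
  }, numeric(1))
  expect_equal(fracBest, c(1, 2 / 3, 1 / 3))
  expect_true(all(diff(fracBest) <= 0))
})

test_that("report, FASTA and BED exports agree row for row", {
  tri <- makeTriangleSeries()
  genome <- randomGenome(2000, seed = 4)
  graded <- gradePeaks(callPeaks(tri$series,
                                 peakCallConfig(20L, statRange = 100L,
                                                minApex = 5)),
                       tri$series, genome = genome, seqRange = 21L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  bed <- withr::local_tempfile(fileext = ".bed")
  writePeakReport(graded, tsv)
  writePeakFasta(graded, fa)
  writePeakBed(graded, bed)

  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(graded))
  expect_equal(back$apex, graded$apex)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_length(seqs, nrow(graded))
  expect_equal(unname(as.character(seqs)), graded$sequence)
  bedGr <- rtracklayer::import(bed)
  expect_length(bedGr, nrow(graded))
  # BED is 0-based half-open on disk; reimport restores 1-based bounds
  expect_equal(BiocGenerics::start(bedGr), graded$left)
  expect_equal(BiocGenerics::end(bedGr), graded$right)
})
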