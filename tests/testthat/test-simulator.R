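test_that("similarity scoring is the scaled positional match sum", {
  # uniform matrix: every base contributes 0.25
  M <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  uni <- similarityModel(M)
  expect_equal(similarityScore("ACGTACGT", uni), 2)  # 0.25 * 8

  # deterministic matrix: perfect match scores n
  det <- similarityModel("ACGTACGT")
  expect_equal(similarityScore("ACGTACGT", det), 8)
  expect_equal(maxSimilarity(det), 8)
  expect_equal(similarityScore("ACGTACGA", det), 7)
  expect_error(similarityScore("ACGT", det), "length")

  # term-by-term oracle on random matrices and sequences
  for (seed in 1:20) {
    withr::with_seed(seed, {
      M <- matrix(runif(32), 4, 8,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
      M <- sweep(M, 2, colSums(M), "/")
      s <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
    })
    model <- similarityModel(M, A = 2)
    chars <- strsplit(s, "")[[1]]
    expected <- 0
    for (i in 1:8) expected <- expected + M[chars[i], i]
    expect_equal(similarityScore(s, model), unname(2 * expected))
  }
})

test_that("similarity scoring agrees with the Biostrings PWM scorer", {
  withr::with_seed(4, {
    M <- matrix(runif(40), 4, 10,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    M <- sweep(M, 2, colSums(M), "/")
    subject <- Biostrings::DNAString(randomGenome(60, seed = 44))
  })
  model <- similarityModel(M)
  for (at in c(1L, 13L, 51L)) {
    s <- as.character(Biostrings::subseq(subject, at, at + 9L))
    expect_equal(similarityScore(s, model),
                 Biostrings::PWMscoreStartingAt(M, subject, starting.at = at),
                 tolerance = 1e-9)
  }
})

test_that("genome similarity profiles find planted motifs on both strands", {
  det <- similarityModel("ACGTTGCA")
  # genome identical to the motif: one window scoring the maximum
  expect_equal(genomeSimilarityProfile("ACGTTGCA", det), 8)

  g <- randomGenome(3000, seed = 6)
  motif <- substr(g, 1200, 1224)
  model <- similarityModel(motif)
  prof <- genomeSimilarityProfile(g, model)
  expect_length(prof, 3000 - 25 + 1)
  expect_equal(which.max(prof), 1200L)
  expect_equal(max(prof), 25)

  # strand symmetry: profile of the reverse-complemented genome is the
  # reversed profile
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  expect_equal(genomeSimilarityProfile(rc, model), rev(prof))
})

test_that("site frequencies cut off below threshold and steepen by round", {
  cfg <- simConfig(genomeSize = 1e4, totalReads = 1e4, cutoffFrac = 0.5,
                   seed = 1)
  maxScore <- 20
  expect_equal(siteFrequency(9.9, 1, cfg, maxScore), 0)  # below 0.5 * 20
  # closed-form ratio between the maximum and the cutoff score
  r <- siteFrequency(20, 2, cfg, maxScore) /
       siteFrequency(10, 2, cfg, maxScore)
  expect_equal(r, exp(cfg@steepness[2] * (1 - cfg@cutoffFrac)))
  # later cycles respond more steeply: cycle-3/cycle-2 ratio grows with score
  s <- seq(10, 20, by = 0.5)
  ratio <- siteFrequency(s, 3, cfg, maxScore) /
           siteFrequency(s, 2, cfg, maxScore)
  expect_true(all(diff(ratio) > 0))
  expect_error(siteFrequency(10, 5, cfg, maxScore), "nCycles")
})

test_that("placed Gaussians carry the right mass, width and truncation", {
  tr <- placeGaussian(numeric(2000), 1000, amplitude = 100, sigma = 10)
  expect_equal(sum(tr), 100 * 10 * sqrt(2 * pi), tolerance = 1e-3)
  expect_equal(which.max(tr), 1000L)
  expect_equal(peakWidth99(tr[tr > 0]), 2 * qnorm(0.995) * 10,
               tolerance = 0.05)

  # truncation at the genome edge, no wraparound
  tr <- placeGaussian(numeric(100), 3, amplitude = 50, sigma = 10)
  expect_lt(sum(tr), 50 * 10 * sqrt(2 * pi))
  expect_gt(tr[1], 0)
  expect_equal(tr[100], 0)
  expect_error(placeGaussian(numeric(10), 5, 1, 0), "sigma")
})

test_that("simulated datasets are deterministic and correctly normalized", {
  cfg <- simConfig(genomeSize = 3e4, totalReads = 1e5, fragmentLength = 50L,
                   motifLenRange = c(16L, 20L), seed = 9L)
  ds1 <- simulateDataset(cfg)
  ds2 <- simulateDataset(cfg)
  expect_identical(as.character(ds1@genome), as.character(ds2@genome))
  for (i in 1:4)
    expect_identical(trackCounts(ds1@series, i), trackCounts(ds2@series, i))
  expect_identical(ds1@truth, ds2@truth)

  # enrichment-track mass is normalized to totalReads * L
  for (i in 2:4)
    expect_equal(sum(trackCounts(ds1@series, i)), 1e5 * 50,
                 tolerance = 1e-3 * 1e-3)

  # the planted motif is a genome substring and the top-scoring truth site
  expect_equal(substr(as.character(ds1@genome[[1]]), ds1@truth$motifStart,
                      ds1@truth$motifStart + ds1@truth$bTrue - 1L),
               ds1@truth$motif)
  expect_true(ds1@truth$motifStart %in% ds1@truth$sites$position)
  expect_equal(max(ds1@truth$sites$similarity), ds1@truth$bTrue)
})

test_that("control coverage is independent of the similarity profile", {
  ds <- smallDataset()
  prof <- genomeSimilarityProfile(ds@genome, similarityModel(ds@truth$motif))
  ctrl <- trackCounts(controlTrack(ds@series))[seq_along(prof)]
  expect_lt(abs(stats::cor(ctrl, prof)), 0.05)
  expect_equal(mean(trackCounts(controlTrack(ds@series))),
               ds@config@controlDepth, tolerance = 0.05)
})

test_that("called peak counts match the truth site count to order of magnitude", {
  ds <- smallDataset()
  peaks <- callPeaks(ds@series,
                     peakCallConfig(fragmentLength(ds@series)))
  ratio <- nrow(peaks) / nrow(ds@truth$sites)
  expect_gte(ratio, 0.1)
  expect_lte(ratio, 10)
})

test_that("Gaussian fit r2 is exact for Gaussians and penalizes misfit", {
  x <- 100 * exp(-((1:1201) - 601)^2 / (2 * 50^2))
  expect_equal(gaussianFitR2(x), 1.0, tolerance = 1e-6)

  rect <- c(numeric(50), rep(10, 100), numeric(50))
  expect_lt(gaussianFitR2(rect), 1)

  # a point mass has zero positional variance: undefined, flagged
  expect_warning(r2 <- gaussianFitR2(c(0, 5, 0)), "variance")
  expect_true(is.na(r2))

  # noisy Gaussian against a direct sum-of-squares computation
  noisy <- withr::with_seed(12, x + rnorm(length(x), sd = 5))
  noisy[noisy < 0] <- 0
  got <- gaussianFitR2(noisy)
  p <- noisy / sum(noisy)
  mu <- sum(seq_along(noisy) * p)
  s2 <- sum((seq_along(noisy) - mu)^2 * p)
  fitted <- max(noisy) * exp(-(seq_along(noisy) - mu)^2 / (2 * s2))
  expected <- 1 - sum((noisy - fitted)^2) / sum((noisy - mean(noisy))^2)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("similarity binning chunks ranked sites and drops partial groups", {
  prof <- withr::with_seed(5, runif(250, 0, 10))
  track <- withr::with_seed(6, runif(300, 0, 100))
  tab <- binnedSimilarityFrequency(prof, track, bin = 100L)
  expect_equal(nrow(tab), 2L)
  expect_true(all(diff(tab$similarity) <= 0))

  # sort-and-chunk oracle
  ord <- order(-prof, seq_along(prof))
  for (gidx in 1:2) {
    take <- ord[((gidx - 1) * 100 + 1):(gidx * 100)]
    expect_equal(tab$similarity[gidx], mean(prof[take]))
    expect_equal(tab$frequency[gidx], mean(track[take]))
  }

  # constant frequency: every bin mean identical
  tabc <- binnedSimilarityFrequency(prof, rep(7, 300), bin = 100L)
  expect_equal(tabc$frequency, rep(7, 2))
  expect_error(binnedSimilarityFrequency(runif(50), track, bin = 100L),
               "full bin")
})

test_that("exponential fits recover exact generating parameters", {
  tab <- data.frame(similarity = seq(1, 10, by = 0.5),
                    frequency = 2 * exp(1.5 * seq(1, 10, by = 0.5)))
  fit <- fitExponential(tab)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$k, 1.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  flat <- data.frame(similarity = 1:10, frequency = rep(4, 10))
  expect_equal(fitExponential(flat)$k, 0, tolerance = 1e-12)

  expect_error(fitExponential(data.frame(similarity = 1:5,
                                         frequency = c(1, 2, 0, 0, 0))),
               ">= 3 bins")
})

test_that("simulated enrichment steepens round over round with tight fits", {
  # A 29-bp motif keeps above-cutoff sites sparse enough (and short
  # fragments keep footprints narrow enough) that a site's frequency is
  # driven by its own similarity rather than by spillover from neighboring
  # peak footprints.
  cfg <- simConfig(genomeSize = 3e5, totalReads = 1e6, fragmentLength = 30L,
                   motifLenRange = c(29L, 29L), cutoffFrac = 0.5, seed = 7L)
  ds <- simulateDataset(cfg)
  prof <- genomeSimilarityProfile(ds@genome, similarityModel(ds@truth$motif))
  off <- round((ds@truth$bTrue - 1) / 2)
  # the exponential response holds over the enriching range; bins are kept
  # only when fully inside it (a boundary bin mixes above-cutoff sites with
  # zero-expectation ones and its mean frequency is meaningless)
  lvl <- ceiling(cfg@cutoffFrac * ds@truth$bTrue + 1e-9)
  ks <- numeric(cfg@nCycles)
  for (cyc in seq_len(cfg@nCycles)) {
    tab <- binnedSimilarityFrequency(prof, trackCounts(ds@series, cyc + 1L),
                                     bin = 100L, offset = off)
    tab <- tab[tab$similarity >= lvl, , drop = FALSE]
    fit <- fitExponential(tab)
    ks[cyc] <- fit$k
    expect_gt(fit$r2, 0.90)
  }
  expect_true(all(diff(ks) > 0))
})
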