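#' Construct a SimConfig
#'
#' Defaults reproduce the reference synthetic-data conditions: a 5e6 bp
#' random genome, a random 15-30 bp substring as the motif of interest,
#' three enrichment cycles on top of the unselected control, per-cycle
#' coverage mass normalized to 2e7 reads-equivalent, and an exponential
#' similarity-to-frequency response whose steepness grows round over round
#' (default schedule 4, 6, 8, ... -- the qualitative property the response
#' must satisfy; override with fitted values when available).
#'
#' The enrichment cutoff sits halfway between the similarity of a random
#' sequence and a perfect match. Under the deterministic motif matrix a
#' random n-mer already matches 25% of positions, so "50% of maximum
#' identity" translates to 0.625 of the raw maximum score
#' (0.25 + 0.5 * 0.75). This calibration keeps above-cutoff site counts in
#' the hundreds-to-thousands per megabase range characteristic of real
#' afSELEX-seq peak sets; cutting at 0.5 of the raw maximum instead admits
#' 2-3% of all genome positions for short motifs, tiling the genome with
#' overlapping footprints that no peak caller could separate.
#'
#' @param genomeSize Genome length in bp (default 5e6).
#' @param motifLenRange Integer range the motif length is drawn from
#'   (default 15-30 bp).
#' @param nCycles Number of enrichment cycles (default 3).
#' @param totalReads Per-cycle read total; each enrichment track's coverage
#'   mass is normalized to `totalReads * fragmentLength` (default 2e7).
#' @param fragmentLength Mean library fragment length in bp (default 100).
#' @param cutoffFrac Fraction of the maximum similarity below which a site
#'   does not enrich (default 0.625, the halfway point between the
#'   random-sequence baseline 0.25 and a perfect match; see Details).
#' @param steepness Per-cycle exponential steepness, strictly increasing;
#'   default `4 + 2 * (0:(nCycles-1))`.
#' @param controlDepth Mean coverage of the unselected control track
#'   (default 20).
#' @param seed Integer seed (default 1).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(genomeSize = 5e6, motifLenRange = c(15L, 30L),
                      nCycles = 3L, totalReads = 2e7,
                      fragmentLength = 100L, cutoffFrac = 0.625,
                      steepness = NULL, controlDepth = 20, seed = 1L) {
  nCycles <- as.integer(nCycles)
  if (is.null(steepness)) steepness <- 4 + 2 * (seq_len(nCycles) - 1)
  new("SimConfig", genomeSize = as.numeric(genomeSize),
      motifLenRange = as.integer(motifLenRange), nCycles = nCycles,
      totalReads = as.numeric(totalReads),
      fragmentLength = as.integer(fragmentLength),
      cutoffFrac = as.numeric(cutoffFrac),
      steepness = as.numeric(steepness),
      controlDepth = as.numeric(controlDepth), seed = as.integer(seed))
}

#' Construct a SimilarityModel
#'
#' From a motif string the model is the deterministic matrix (probability 1
#' on the motif base at each position), under which the similarity of an
#' n-mer reduces to `A` times its match count to the motif. A 4 x n
#' probability matrix (rows A, C, G, T) may be supplied instead.
#'
#' @param x Motif as a character string, or a 4 x n column-stochastic
#'   matrix with rows named A, C, G, T.
#' @param A Positive scaling factor (default 1).
#' @return A [SimilarityModel-class].
#' @examples
#' similarityModel("ACGT")
#' @export
similarityModel <- function(x, A = 1) {
  if (is.character(x)) {
    chars <- strsplit(toupper(x), "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    if (anyNA(idx)) stop("motif must be over A/C/G/T")
    M <- matrix(0, nrow = 4, ncol = length(chars),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    M[cbind(idx, seq_along(idx))] <- 1
  } else {
    M <- x
  }
  new("SimilarityModel", matrix = M, scale = as.numeric(A))
}

#' Maximum attainable similarity score of a model
#'
#' @param model A [SimilarityModel-class].
#' @return `A * sum_i max_c M[c, i]`.
#' @export
maxSimilarity <- function(model) {
  model@scale * sum(apply(model@matrix, 2, max))
}

#' Similarity of one sequence to a positional weight matrix
#'
#' The linear matching score `A * sum_i M[S[i], i]`: each position
#' contributes the matrix probability of the observed base, scaled by A.
#' Non-ACGT characters contribute zero.
#'
#' @param sequence Character n-mer (n = model width).
#' @param model A [SimilarityModel-class].
#' @return A single numeric score.
#' @examples
#' m <- similarityModel("ACGTACGT")
#' similarityScore("ACGTACGT", m)  # 8, the maximum
#' @export
similarityScore <- function(sequence, model) {
  M <- model@matrix
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) != ncol(M))
    stop("sequence length ", length(chars), " != model width ", ncol(M))
  idx <- match(chars, c("A", "C", "G", "T"))
  hit <- !is.na(idx)
  model@scale * sum(M[cbind(idx[hit], seq_along(idx)[hit])])
}

#' Per-position similarity profile of a genome
#'
#' Scores the window starting at every genome position against the model on
#' both strands (the reverse-complement window against the same matrix) and
#' keeps the larger score -- dsDNA binding is strand-agnostic. Profile
#' length is `G - n + 1`.
#'
#' @param genome Genome as [Biostrings::DNAStringSet], `DNAString` or
#'   character.
#' @param model A [SimilarityModel-class].
#' @return Numeric vector of similarity scores, one per window start.
#' @export
genomeSimilarityProfile <- function(genome, model) {
  g <- .genomeAsString(genome)
  G <- nchar(g)
  n <- ncol(model@matrix)
  if (G < n) stop("genome shorter than the motif")
  code <- match(strsplit(g, "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  score1 <- function(M) {
    Mpad <- unname(rbind(M, 0))
    acc <- numeric(G - n + 1L)
    for (i in seq_len(n)) {
      col <- Mpad[, i]
      acc <- acc + col[code[i:(G - n + i)]]
    }
    acc
  }
  fwd <- score1(model@matrix)
  # reverse strand: same as scoring each window against the
  # reverse-complemented matrix (rows A<->T, C<->G; columns reversed)
  Mrc <- model@matrix[4:1, rev(seq_len(n)), drop = FALSE]
  rev <- score1(Mrc)
  model@scale * pmax(fwd, rev)
}

#' Expected relative site frequency in an enrichment cycle
#'
#' Sites scoring below `cutoffFrac` of the maximum similarity do not enrich
#' (frequency 0); above the cutoff the expected frequency is proportional
#' to `exp(k_c * score / maxScore)` with the cycle steepness `k_c` strictly
#' increasing over rounds, so the similarity-frequency response grows
#' steeper with every round of selection. Absolute scale is fixed later by
#' track normalization.
#'
#' @param score Numeric similarity score(s).
#' @param cycleIndex Enrichment cycle index (1 = first enrichment cycle).
#' @param config A [SimConfig-class].
#' @param maxScore Maximum similarity score in the dataset.
#' @return Numeric relative frequency (0 below cutoff).
#' @export
siteFrequency <- function(score, cycleIndex, config, maxScore) {
  if (cycleIndex < 1L || cycleIndex > config@nCycles)
    stop("cycleIndex must be in 1..nCycles")
  ifelse(score < config@cutoffFrac * maxScore, 0,
         exp(config@steepness[cycleIndex] * score / maxScore))
}

#' Add a truncated Gaussian peak to a track
#'
#' Adds `amplitude * exp(-(x - center)^2 / (2 sigma^2))` over positions
#' within 4 sigma of the center, truncated at the genome ends (no
#' wraparound).
#'
#' @param counts Numeric track vector.
#' @param center Peak center (1-based position; may be fractional).
#' @param amplitude Peak height.
#' @param sigma Gaussian SD (bp); > 0.
#' @return The updated track vector.
#' @export
placeGaussian <- function(counts, center, amplitude, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  G <- length(counts)
  lo <- max(1L, as.integer(ceiling(center - 4 * sigma)))
  hi <- min(G, as.integer(floor(center + 4 * sigma)))
  if (lo > hi) return(counts)
  x <- lo:hi
  counts[x] <- counts[x] + amplitude * exp(-(x - center)^2 / (2 * sigma^2))
  counts
}

#' Simulate a synthetic afSELEX-seq dataset
#'
#' Generates a uniform random genome; plants the motif of interest as a
#' random genome substring of random length in `motifLenRange`; scores
#' every position for similarity to the motif ([genomeSimilarityProfile()]);
#' and, for each enrichment cycle, places a Gaussian peak at every
#' above-cutoff site with amplitude from [siteFrequency()], then normalizes
#' the track's total mass to `totalReads * fragmentLength` (the coverage
#' equivalent of a fixed per-cycle read total). The Gaussian SD is
#' `(2L - b) / (2 * qnorm(0.995))` so the central 99% of each peak's area
#' spans the fragment footprint `2L - b` of the true site. The control
#' track is uniform random integer coverage with mean `controlDepth`,
#' independent of similarity (no selection has yet occurred).
#'
#' @param config A [SimConfig-class].
#' @return A [SyntheticDataset-class] with ground truth (`truth` slot:
#'   motif, its length and position, and all above-cutoff sites with their
#'   similarities).
#' @examples
#' ds <- simulateDataset(simConfig(genomeSize = 2e4, totalReads = 2e4,
#'                                 fragmentLength = 50L, seed = 7L))
#' ds
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  G <- as.integer(config@genomeSize)
  L <- config@fragmentLength
  .withSeed(config@seed, {
    genomeChars <- sample(c("A", "C", "G", "T"), G, replace = TRUE)
    genome <- paste(genomeChars, collapse = "")
    lenChoices <- seq.int(config@motifLenRange[1], config@motifLenRange[2])
    bTrue <- lenChoices[sample.int(length(lenChoices), 1L)]
    motifStart <- sample.int(G - bTrue + 1L, 1L)
    motif <- substr(genome, motifStart, motifStart + bTrue - 1L)
    model <- similarityModel(motif)
    profile <- genomeSimilarityProfile(genome, model)
    maxScore <- max(profile)
    sites <- which(profile >= config@cutoffFrac * maxScore)
    if (length(sites) == 0L)
      stop("no site reaches the enrichment cutoff; lower cutoffFrac")
    sims <- profile[sites]
    centers <- round(sites + (bTrue - 1) / 2)
    sigma <- (2 * L - bTrue) / .CENTRAL99
    if (sigma <= 0)
      stop("fragmentLength too small for the drawn motif length")

    # Equivalent to one placeGaussian() per site, but placed in a single
    # sweep over kernel offsets (all sites share sigma).
    h <- as.integer(floor(4 * sigma))
    kernel <- exp(-(-h:h)^2 / (2 * sigma^2))
    enrich <- lapply(seq_len(config@nCycles), function(cyc) {
      amps <- siteFrequency(sims, cyc, config, maxScore)
      track <- numeric(G)
      for (d in -h:h) {
        idx <- centers + d
        inb <- idx >= 1L & idx <= G
        track[idx[inb]] <- track[idx[inb]] + amps[inb] * kernel[d + h + 1L]
      }
      track * (config@totalReads * L / sum(track))
    })
    control <- as.numeric(
      sample.int(2 * round(config@controlDepth) + 1L, G, replace = TRUE) - 1L)

    tracksList <- c(
      list(FrequencyTrack(control, cycle = 1L)),
      lapply(seq_along(enrich), function(i)
        FrequencyTrack(enrich[[i]], cycle = i + 1L)))
    new("SyntheticDataset",
        genome = Biostrings::DNAStringSet(stats::setNames(genome, "synthetic")),
        series = CycleSeries(tracksList, L),
        truth = list(motif = motif, bTrue = as.integer(bTrue),
                     motifStart = as.integer(motifStart),
                     sites = data.frame(position = sites,
                                        similarity = sims)),
        config = config)
  })
}

#' Goodness of Gaussian fit of a peak profile
#'
#' Parameterizes a Gaussian by the profile's own maximum (amplitude), mean
#' position and positional SD (moments of the profile treated as a mass
#' distribution), and reports the least-squares r-squared between the
#' profile and that Gaussian -- an estimate of how normal the peak's shape
#' is.
#'
#' @param x Numeric profile across a peak (>= 3 positions, positive mass).
#' @return r-squared in (-Inf, 1]; `NA` (with a warning) for zero-variance
#'   profiles.
#' @examples
#' gaussianFitR2(dnorm(seq(-6, 6, by = 0.01)))  # 1 (exact Gaussian)
#' @export
gaussianFitR2 <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("profile needs >= 3 positions")
  total <- sum(x)
  if (!is.finite(total) || total <= 0)
    stop("profile must carry positive mass")
  pos <- seq_along(x)
  p <- x / total
  mu <- sum(pos * p)
  s2 <- sum((pos - mu)^2 * p)
  if (s2 == 0) {
    warning("zero positional variance; Gaussian fit undefined")
    return(NA_real_)
  }
  fitted <- max(x) * exp(-(pos - mu)^2 / (2 * s2))
  1 - sum((x - fitted)^2) / sum((x - mean(x))^2)
}

#' Bin sites by similarity rank and average frequency per bin
#'
#' Ranks all sites by descending similarity to the motif, groups them into
#' consecutive bins of `bin` sites (trailing partial bin dropped) and
#' returns per-bin mean similarity and mean track frequency -- the table a
#' similarity-to-frequency regression is fitted to.
#'
#' @param profile Numeric per-site similarity scores (site start positions
#'   1..length(profile)).
#' @param track A [FrequencyTrack-class] or numeric counts vector.
#' @param bin Sites per bin (default 100).
#' @param offset Integer offset from a site's start to the track position
#'   read as its frequency (default 0; use the site midpoint offset when
#'   peak mass is centered mid-site).
#' @return A data.frame with columns `similarity` and `frequency`, rows in
#'   descending similarity order.
#' @export
binnedSimilarityFrequency <- function(profile, track, bin = 100L,
                                      offset = 0L) {
  counts <- .asCounts(track)
  nsites <- length(profile)
  if (nsites < bin) stop("need at least one full bin of sites")
  pos <- pmin(pmax(seq_len(nsites) + as.integer(offset), 1L),
              length(counts))
  freq <- counts[pos]
  ord <- order(-profile, seq_len(nsites))
  ngrp <- nsites %/% bin
  take <- ord[seq_len(ngrp * bin)]
  grp <- rep(seq_len(ngrp), each = bin)
  data.frame(
    similarity = as.numeric(tapply(profile[take], grp, mean)),
    frequency = as.numeric(tapply(freq[take], grp, mean)))
}

#' Fit an exponential similarity-to-frequency model
#'
#' Fits `frequency = a * exp(k * similarity)` by least squares on the log
#' scale, using rows with positive frequency, and reports the log-scale
#' r-squared.
#'
#' @param table Binned table from [binnedSimilarityFrequency()] (or any
#'   data.frame with `similarity` and `frequency`).
#' @return List with `a`, `k` and `r2`.
#' @examples
#' tab <- data.frame(similarity = 1:10,
#'                   frequency = 2 * exp(1.5 * (1:10)))
#' fitExponential(tab)  # a = 2, k = 1.5, r2 = 1
#' @export
fitExponential <- function(table) {
  use <- table[is.finite(table$frequency) & table$frequency > 0, ,
               drop = FALSE]
  if (nrow(use) < 3L)
    stop("need >= 3 bins with positive frequency; got ", nrow(use))
  fit <- lm(log(frequency) ~ similarity, data = use)
  # noiseless tables fit exactly; lm's perfect-fit caveat is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(a = unname(exp(coef(fit)[1])), k = unname(coef(fit)[2]), r2 = r2)
}
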