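#' Construct ScoringWeights
#'
#' By default the weight doubles with every transition (1, 2, 4, ...), a
#' proxy for the increasing bulk affinity -- and hence stringency of
#' competition -- of later rounds; supply measured bulk affinities via `w`
#' when available.
#'
#' @param nTransitions Integer number of cycle transitions (cycles - 1).
#' @param w Numeric vector of positive per-transition weights; default
#'   `2^(0:(nTransitions-1))`.
#' @param enrichFactor Minimal fold-change to count as enrichment (default
#'   1: strictly greater).
#' @return A [ScoringWeights-class].
#' @export
scoringWeights <- function(nTransitions, w = 2^(seq_len(nTransitions) - 1),
                           enrichFactor = 1) {
  new("ScoringWeights", w = as.numeric(w),
      enrichFactor = as.numeric(enrichFactor))
}

#' Cumulative round-weighted enrichment score
#'
#' A peak scores the weight of every transition in which its apex frequency
#' enriched, i.e. `score = sum_t w[t] * [freq[t+1] > enrichFactor * freq[t]]`
#' over transitions t (control to cycle 2, cycle 2 to 3, ...). Sequences
#' that stay competitive throughout the experiment accumulate the largest
#' scores.
#'
#' @param cycleFreqs Numeric vector of apex frequencies, control first.
#' @param weights A [ScoringWeights-class] with one weight per transition.
#' @return A single numeric score.
#' @examples
#' enrichmentScore(c(10, 20, 40, 80), scoringWeights(3))  # 7
#' enrichmentScore(c(10, 20, 15, 80), scoringWeights(3))  # 5
#' @export
enrichmentScore <- function(cycleFreqs, weights) {
  w <- weights@w
  if (length(cycleFreqs) != length(w) + 1L)
    stop("need one frequency per cycle: got ", length(cycleFreqs),
         " frequencies for ", length(w), " transition weights")
  f <- as.numeric(cycleFreqs)
  enriched <- f[-1] > weights@enrichFactor * f[-length(f)]
  sum(w[enriched])
}

#' Assign ordinal quality classes from scores
#'
#' Distinct achieved scores, sorted descending, define classes 1..k: class 1
#' ("Best") is the maximal achieved score, class 2 the second best, and so
#' on. With a single transition every called peak that enriches once shares
#' the top score, so all fall in class 1.
#'
#' @param scores Numeric vector of peak scores.
#' @return Integer vector of class labels (1 = "Best").
#' @examples
#' assignClasses(c(7, 7, 5, 1))  # 1 1 2 3
#' @export
assignClasses <- function(scores) {
  if (length(scores) == 0L) return(integer(0))
  uniq <- sort(unique(scores), decreasing = TRUE)
  match(scores, uniq)
}

#' Area fractions over a peak set
#'
#' @param areas Numeric vector of per-peak areas (sum of final-cycle counts
#'   over each support).
#' @return Numeric vector of fractions summing to 1.
#' @export
areaFractions <- function(areas) {
  total <- sum(areas)
  if (!is.finite(total) || total <= 0)
    stop("total peak area must be positive")
  areas / total
}

#' Whole-bp width of the central 99% of a peak's area
#'
#' Treats the counts over the peak support as a mass density (position j
#' occupying the unit interval (j-1, j]), locates the 0.5% and 99.5%
#' quantiles of the cumulative distribution by linear interpolation, and
#' returns the width of the smallest whole-bp chromosome range containing
#' that central 99% interval. For a peak over a single binding site of
#' length b covered by fragments of mean length L, this width approximates
#' the full footprint 2L - b.
#'
#' @param x Numeric vector of counts across the peak support (positive
#'   total mass).
#' @param coverage Central mass fraction to span (default 0.99).
#' @return Integer width in bp.
#' @examples
#' peakWidth99(rep(1, 100))  # 100: flat footprints keep their full width
#' peakWidth99(c(0, 50, 0))  # 1: point mass
#' @export
peakWidth99 <- function(x, coverage = 0.99) {
  x <- as.numeric(x)
  total <- sum(x)
  if (!is.finite(total) || total <= 0)
    stop("peak support must carry positive mass")
  cum <- cumsum(x)
  tail <- (1 - coverage) / 2
  qat <- function(t) {
    j <- which(cum >= t)[1]
    prev <- if (j > 1L) cum[j - 1L] else 0
    (j - 1) + (t - prev) / x[j]
  }
  qlo <- qat(tail * total)
  qhi <- qat((1 - tail) * total)
  as.integer(ceiling(qhi - 1e-9) - floor(qlo + 1e-9))
}

#' Predict binding-site length from peak width
#'
#' A dsDNA fragment only binds specifically if it contains the whole
#' binding site, so fragments of mean length L covering a site of length b
#' pile up into a footprint of full width W = 2L - b; inverting gives
#' b = 2L - W. Predictions at or below zero (peak wider than two fragment
#' lengths) are clamped to 0 and flagged indeterminate.
#'
#' @param width Numeric peak width W (bp), e.g. from [peakWidth99()].
#' @param fragmentLength Integer mean library fragment length L (bp).
#' @return A list with `length` (predicted b, bp, >= 0) and `indeterminate`
#'   (logical). Both are vectorized over `width`.
#' @examples
#' predictBindingLength(172, 100)  # length 28
#' predictBindingLength(200, 100)  # length 0, indeterminate
#' @export
predictBindingLength <- function(width, fragmentLength) {
  raw <- 2 * fragmentLength - width
  list(length = pmax(0, round(raw)), indeterminate = raw <= 0)
}

#' Genomic sequence under a peak
#'
#' @param genome Genome as a [Biostrings::DNAStringSet], `DNAString` or
#'   character string.
#' @param apex Integer 1-based apex position(s).
#' @param seqRange Integer length (bp) of sequence to extract, centered on
#'   the apex; clipped at the genome ends.
#' @return Character vector of uppercase sequences.
#' @export
peakSequence <- function(genome, apex, seqRange) {
  if (seqRange < 1L) stop("seqRange must be >= 1")
  g <- .genomeAsString(genome)
  G <- nchar(g)
  half <- (seqRange - 1L) %/% 2L
  from <- pmax(apex - half, 1L)
  to <- pmin(apex + (seqRange - 1L - half), G)
  substring(g, from, to)
}

#' Grade called peaks by inter-cycle enrichment
#'
#' Annotates every candidate peak with its apex frequency in each cycle,
#' the cumulative round-weighted enrichment score, an ordinal quality class
#' (1 = "Best" = maximal achieved score), its area and area fraction in the
#' final cycle, the width of the central 99% of its area, the predicted
#' binding-site length `2L - width`, and (when a genome is supplied) the
#' genomic sequence centered on its apex. The report is hierarchical: rows
#' are ordered by class, then score descending, then area descending, then
#' position.
#'
#' @param peaks Candidate peak data.frame from [callPeaks()].
#' @param series The [CycleSeries-class] the peaks were called on.
#' @param weights A [ScoringWeights-class]; defaults to doubling weights
#'   over the series' transitions.
#' @param genome Optional genome (see [peakSequence()]).
#' @param seqRange Integer length of the reported peak sequence (default
#'   200 bp, sized for motif-discovery input).
#' @return A data.frame with one row per peak and columns `rank`, `class`,
#'   `score`, `apex`, `apexFreq`, `freq.cycle<i>`..., `area`,
#'   `areaFraction`, `width99`, `predictedLength`, `indeterminate`, `left`,
#'   `right`, `sequence`.
#' @export
gradePeaks <- function(peaks, series,
                       weights = scoringWeights(nCycles(series) - 1L),
                       genome = NULL, seqRange = 200L) {
  k <- nCycles(series)
  if (length(weights@w) != k - 1L)
    stop("need one weight per cycle transition: ", k - 1L, " transitions, ",
         length(weights@w), " weights")
  cols <- paste0("freq.cycle", seq_len(k))
  if (nrow(peaks) == 0L) {
    out <- data.frame(rank = integer(0), class = integer(0),
                      score = numeric(0), apex = integer(0),
                      apexFreq = numeric(0))
    for (cl in cols) out[[cl]] <- numeric(0)
    out$area <- numeric(0); out$areaFraction <- numeric(0)
    out$width99 <- integer(0); out$predictedLength <- numeric(0)
    out$indeterminate <- logical(0)
    out$left <- integer(0); out$right <- integer(0)
    out$sequence <- character(0)
    return(out)
  }

  freqs <- vapply(tracks(series),
                  function(t) t@counts[peaks$apex], numeric(nrow(peaks)))
  freqs <- matrix(freqs, nrow = nrow(peaks), ncol = k)
  enriched <- freqs[, -1, drop = FALSE] >
    weights@enrichFactor * freqs[, -k, drop = FALSE]
  score <- as.numeric(enriched %*% weights@w)
  cls <- assignClasses(score)

  final <- trackCounts(finalTrack(series))
  cs <- c(0, cumsum(final))
  area <- cs[peaks$right + 1L] - cs[peaks$left]
  areaFrac <- areaFractions(area)
  width99 <- vapply(seq_len(nrow(peaks)), function(i) {
    peakWidth99(final[peaks$left[i]:peaks$right[i]])
  }, integer(1))
  pred <- predictBindingLength(width99, fragmentLength(series))
  seqs <- if (is.null(genome)) rep(NA_character_, nrow(peaks))
          else peakSequence(genome, peaks$apex, seqRange)

  out <- data.frame(rank = NA_integer_, class = cls, score = score,
                    apex = peaks$apex, apexFreq = peaks$apexFreq)
  for (i in seq_len(k)) out[[cols[i]]] <- freqs[, i]
  out$area <- area
  out$areaFraction <- areaFrac
  out$width99 <- width99
  out$predictedLength <- pred$length
  out$indeterminate <- pred$indeterminate
  out$left <- peaks$left
  out$right <- peaks$right
  out$sequence <- seqs

  out <- out[order(out$class, -out$score, -out$area, out$apex), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write the hierarchical tab-delimited peak report
#'
#' One row per graded peak, in report order, with 1-based coordinates;
#' designed to feed downstream motif-discovery tooling.
#'
#' @param graded Graded peak data.frame from [gradePeaks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePeakReport <- function(graded, path) {
  write.table(graded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write peak sequences as FASTA
#'
#' Headers follow `peak<rank>|<apex>|<class>|<score>`, sized for direct use
#' as motif-discovery input.
#'
#' @inheritParams writePeakReport
#' @return `path`, invisibly.
#' @export
writePeakFasta <- function(graded, path) {
  seqs <- Biostrings::DNAStringSet(graded$sequence)
  names(seqs) <- sprintf("peak%d|%d|%d|%g", graded$rank, graded$apex,
                         graded$class, graded$score)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Graded peaks as GRanges
#'
#' @inheritParams writePeakReport
#' @param seqname Chromosome name to attach (default "genome").
#' @return A [GenomicRanges::GRanges] of peak supports with grading columns.
#' @export
peaksAsGRanges <- function(graded, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(graded$left, graded$right,
                              names = paste0("peak", graded$rank)))
  gr$score <- graded$score
  gr$class <- graded$class
  gr$apex <- graded$apex
  gr
}

#' Write peak supports as BED
#'
#' @inheritParams peaksAsGRanges
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(graded, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(graded$left, graded$right,
                              names = paste0("peak", graded$rank)),
    score = graded$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
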