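#' Construct a PeakCallConfig
#'
#' @param fragmentLength Integer mean library fragment length L (bp).
#' @param statRange Integer radius (bp) of the control-statistics window
#'   around a candidate apex (default 1000).
#' @param minApex Numeric floor on the calling threshold (default 10
#'   counts), applied when the local control window is degenerate (e.g. all
#'   zero after counter-selection).
#' @param sdMultiplier Numeric number of control SDs above the control mean
#'   a maximum must exceed to be called (default 2).
#' @return A [PeakCallConfig-class].
#' @export
peakCallConfig <- function(fragmentLength, statRange = 1000L, minApex = 10,
                           sdMultiplier = 2) {
  new("PeakCallConfig", fragmentLength = as.integer(fragmentLength),
      statRange = as.integer(statRange), minApex = as.numeric(minApex),
      sdMultiplier = as.numeric(sdMultiplier))
}

#' Local control-cycle calling threshold
#'
#' The calling threshold at a genome position is `mean + sdMultiplier * SD`
#' of the control (unselected) cycle counts over the window
#' `[center - statRange, center + statRange]` (clipped at the genome ends;
#' population SD), but never below `minApex`. Two SDs above the local
#' control mean corresponds to the upper bound of the 95% band of control
#' variation.
#'
#' @param control A [FrequencyTrack-class] or numeric vector of control
#'   counts.
#' @param centers Integer vector of 1-based positions to evaluate.
#' @param config A [PeakCallConfig-class].
#' @return Numeric vector of thresholds, one per center.
#' @export
controlThreshold <- function(control, centers, config) {
  x <- .asCounts(control)
  G <- length(x)
  centers <- as.integer(centers)
  if (any(centers < 1L | centers > G))
    stop("centers must lie within the genome")
  lo <- pmax(centers - config@statRange, 1L)
  hi <- pmin(centers + config@statRange, G)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  n <- hi - lo + 1
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  mu <- s / n
  v <- pmax(s2 / n - mu * mu, 0)  # population variance; clip fp negatives
  pmax(mu + config@sdMultiplier * sqrt(v), config@minApex)
}

#' Sliding-window strict maxima of a frequency track
#'
#' Scans the track in single-nucleotide steps with a centered window of
#' total width twice the fragment length (`fragmentLength` bp to each side)
#' and reports positions that are strict maxima of their window. A position
#' qualifies iff it strictly exceeds every count in the left half-window,
#' weakly exceeds the right half-window, and strictly exceeds the window
#' minimum. The last two clauses implement the plateau rule: an extended
#' run of tied maximal values is reported once, at its leftmost position,
#' while a fully flat window yields nothing.
#'
#' @param x A [FrequencyTrack-class] or numeric count vector (the final
#'   enrichment cycle).
#' @param config A [PeakCallConfig-class] (only `fragmentLength` is used),
#'   or a single integer fragment length.
#' @return Sorted integer vector of 1-based apex positions.
#' @seealso [callPeaks()]
#' @export
findMaxima <- function(x, config) {
  counts <- .asCounts(x)
  L <- if (is(config, "PeakCallConfig")) config@fragmentLength
       else as.integer(config)
  ext <- .neighborMax(counts, L)
  mn <- .neighborMax(-counts, L)
  leftMin <- -mn$left
  rightMin <- -mn$right
  winMin <- pmin(leftMin, rightMin, counts)
  which(counts > ext$left & counts >= ext$right & counts > winMin)
}

#' Delimit maxima into individual peaks
#'
#' Maxima closer together than one fragment length are merged into a single
#' peak (the higher apex is kept), with two exceptions under which both are
#' retained as separate peaks: a deep valley between them (minimum track
#' value below 50% of the smaller apex) or comparable heights (smaller
#' apex at or above 75% of the larger). Merging proceeds left to right;
#' after a merge the surviving apex is compared with the next maximum.
#'
#' Each retained peak is then assigned a support interval: from its apex
#' outwards to the nearest zero-count position, clipped at the midpoint to
#' each retained neighbor, so supports are disjoint and contain only the
#' contiguous non-zero region attributed to that peak.
#'
#' @param maxima Sorted integer vector of apex positions (as from
#'   [findMaxima()]).
#' @param x A [FrequencyTrack-class] or numeric count vector the maxima were
#'   found in.
#' @param config A [PeakCallConfig-class], or a single integer fragment
#'   length.
#' @return A data.frame of candidate peaks with columns `apex`, `apexFreq`,
#'   `left`, `right` (1-based, inclusive).
#' @export
delimitPeaks <- function(maxima, x, config) {
  counts <- .asCounts(x)
  L <- if (is(config, "PeakCallConfig")) config@fragmentLength
       else as.integer(config)
  empty <- data.frame(apex = integer(0), apexFreq = numeric(0),
                      left = integer(0), right = integer(0))
  if (length(maxima) == 0L) return(empty)
  maxima <- as.integer(sort(maxima))

  retained <- integer(length(maxima))
  k <- 0L
  cur <- maxima[1]
  for (m in maxima[-1]) {
    if (m - cur >= L) {
      k <- k + 1L; retained[k] <- cur; cur <- m
      next
    }
    fa <- counts[cur]; fb <- counts[m]
    lo <- min(fa, fb); hi <- max(fa, fb)
    valley <- min(counts[cur:m])
    if (valley < 0.5 * lo || lo >= 0.75 * hi) {
      # deep valley or comparable heights: both stand as separate peaks
      k <- k + 1L; retained[k] <- cur; cur <- m
    } else {
      cur <- if (fb > fa) m else cur  # merge, keep the higher apex
    }
  }
  k <- k + 1L; retained[k] <- cur
  apex <- retained[seq_len(k)]

  G <- length(counts)
  zpos <- which(counts == 0)
  # nearest zero strictly left of apex / strictly right of apex
  il <- findInterval(apex - 1L, zpos)
  zl <- ifelse(il >= 1L, zpos[pmax(il, 1L)], 0L)
  ir <- findInterval(apex, zpos) + 1L
  zr <- ifelse(ir <= length(zpos), zpos[pmin(ir, length(zpos))], G + 1L)
  if (length(zpos) == 0L) {
    zl <- rep(0L, length(apex))
    zr <- rep(G + 1L, length(apex))
  }

  midL <- c(0L, as.integer(floor((apex[-length(apex)] + apex[-1]) / 2)))
  midR <- c(as.integer(floor((apex[-length(apex)] + apex[-1]) / 2)),
            G + 1L)
  left <- pmax(zl + 1L, midL + 1L, 1L)
  right <- pmin(zr - 1L, midR, G)
  data.frame(apex = apex, apexFreq = counts[apex],
             left = as.integer(left), right = as.integer(right))
}

#' Call peaks in the final enrichment cycle of a series
#'
#' Composition of the sliding-window scan, the control-cycle threshold and
#' the spacing/valley/adjacency delimiting rules: strict window maxima of
#' the final cycle are kept where they exceed the local control threshold
#' ([controlThreshold()]) at the apex, then delimited into individual peaks
#' ([delimitPeaks()]).
#'
#' @param series A [CycleSeries-class]; its first track is the unselected
#'   control and its last the final enrichment cycle.
#' @param config A [PeakCallConfig-class]; defaults to
#'   `peakCallConfig(fragmentLength(series))`.
#' @return A data.frame of candidate peaks (columns `apex`, `apexFreq`,
#'   `left`, `right`, `threshold`), sorted by position.
#' @examples
#' ctrl <- FrequencyTrack(rep(1, 400), cycle = 1L)
#' fin <- numeric(400); fin[191:210] <- c(1:10, 10:1) * 10
#' series <- CycleSeries(list(ctrl, FrequencyTrack(fin, cycle = 2L)), 20)
#' callPeaks(series, peakCallConfig(20, statRange = 50, minApex = 5))
#' @export
callPeaks <- function(series, config = peakCallConfig(fragmentLength(series))) {
  final <- trackCounts(finalTrack(series))
  control <- trackCounts(controlTrack(series))
  maxima <- findMaxima(final, config)
  if (length(maxima)) {
    thr <- controlThreshold(control, maxima, config)
    keep <- final[maxima] > thr
    maxima <- maxima[keep]
    thr <- thr[keep]
  } else {
    thr <- numeric(0)
  }
  peaks <- delimitPeaks(maxima, final, config)
  peaks$threshold <- thr[match(peaks$apex, maxima)]
  peaks
}
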