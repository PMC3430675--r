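#' @name afselex-accessors
#' @title Accessors for afselex classes
#'
#' @description Small accessor generics: `trackCounts()` returns the numeric
#' coverage vector of a track (or of one cycle of a series), `trackCycle()`
#' and `nReads()` its cycle index and contributing read count, `tracks()`
#' the track list of a [CycleSeries-class], `fragmentLength()` the mean
#' library fragment length, `genomeLength()` the common track length,
#' `nCycles()` the number of tracks, and `controlTrack()` / `finalTrack()`
#' the first and last track of a series.
#'
#' @param x A [FrequencyTrack-class] or [CycleSeries-class] object.
#' @param i For `trackCounts()` on a series: which cycle (list index).
#' @return See description; vectors, integers or [FrequencyTrack-class]
#'   objects.
#' @examples
#' tr <- FrequencyTrack(c(0, 1, 2, 1, 0), cycle = 1L, nReads = 2L)
#' trackCounts(tr)
#' nReads(tr)
NULL

#' @rdname afselex-accessors
#' @export
setGeneric("trackCounts", function(x, i) standardGeneric("trackCounts"))
#' @rdname afselex-accessors
#' @export
setGeneric("trackCycle", function(x) standardGeneric("trackCycle"))
#' @rdname afselex-accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))
#' @rdname afselex-accessors
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))
#' @rdname afselex-accessors
#' @export
setGeneric("fragmentLength", function(x) standardGeneric("fragmentLength"))
#' @rdname afselex-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname afselex-accessors
#' @export
setGeneric("nCycles", function(x) standardGeneric("nCycles"))
#' @rdname afselex-accessors
#' @export
setGeneric("controlTrack", function(x) standardGeneric("controlTrack"))
#' @rdname afselex-accessors
#' @export
setGeneric("finalTrack", function(x) standardGeneric("finalTrack"))

#' @rdname afselex-accessors
#' @export
setMethod("trackCounts", "FrequencyTrack", function(x, i) x@counts)
#' @rdname afselex-accessors
#' @export
setMethod("trackCounts", "CycleSeries",
          function(x, i) x@tracks[[i]]@counts)
#' @rdname afselex-accessors
#' @export
setMethod("trackCycle", "FrequencyTrack", function(x) x@cycle)
#' @rdname afselex-accessors
#' @export
setMethod("nReads", "FrequencyTrack", function(x) x@nReads)
#' @rdname afselex-accessors
#' @export
setMethod("tracks", "CycleSeries", function(x) x@tracks)
#' @rdname afselex-accessors
#' @export
setMethod("fragmentLength", "CycleSeries", function(x) x@fragmentLength)
#' @rdname afselex-accessors
#' @export
setMethod("genomeLength", "FrequencyTrack", function(x) length(x@counts))
#' @rdname afselex-accessors
#' @export
setMethod("genomeLength", "CycleSeries",
          function(x) length(x@tracks[[1]]@counts))
#' @rdname afselex-accessors
#' @export
setMethod("nCycles", "CycleSeries", function(x) length(x@tracks))
#' @rdname afselex-accessors
#' @export
setMethod("controlTrack", "CycleSeries", function(x) x@tracks[[1]])
#' @rdname afselex-accessors
#' @export
setMethod("finalTrack", "CycleSeries",
          function(x) x@tracks[[length(x@tracks)]])

setMethod("show", "FrequencyTrack", function(object) {
  cat(sprintf(
    "FrequencyTrack: cycle %d, %d positions, %s reads, total mass %.4g\n",
    object@cycle, length(object@counts),
    ifelse(is.na(object@nReads), "NA", format(object@nReads)),
    sum(object@counts)))
})

setMethod("show", "CycleSeries", function(object) {
  cat(sprintf(
    "CycleSeries: %d cycles (control + %d), genome %d bp, fragment length %d bp\n",
    length(object@tracks), length(object@tracks) - 1L,
    genomeLength(object), object@fragmentLength))
})

setMethod("show", "PeakCallConfig", function(object) {
  cat(sprintf(
    "PeakCallConfig: L=%d bp (window 2L), statRange=%d bp, threshold mean + %g SD (floor %g)\n",
    object@fragmentLength, object@statRange, object@sdMultiplier,
    object@minApex))
})

setMethod("show", "ScoringWeights", function(object) {
  cat(sprintf("ScoringWeights: %s (enrichment fold > %g)\n",
              paste(object@w, collapse = ", "), object@enrichFactor))
})

setMethod("show", "ZeroOrderModel", function(object) {
  cat("ZeroOrderModel:",
      paste(sprintf("%s=%.4f", names(object@p), object@p), collapse = " "),
      "\n")
})

setMethod("show", "SpoofSet", function(object) {
  cat(sprintf("SpoofSet: %d spoof peaks of %d bp (seed %d)\n",
              length(object@positions), object@seqRange, object@seed))
})

setMethod("show", "SimilarityModel", function(object) {
  cat(sprintf("SimilarityModel: %d positions, scale A=%g, max score %g\n",
              ncol(object@matrix), object@scale, maxSimilarity(object)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    paste0("SimConfig: genome %g bp, motif %d-%d bp, %d enrichment cycles, ",
           "%g reads/cycle, L=%d bp,\n  cutoff %g of max similarity, ",
           "steepness (%s), control depth %g, seed %d\n"),
    object@genomeSize, object@motifLenRange[1], object@motifLenRange[2],
    object@nCycles, object@totalReads, object@fragmentLength,
    object@cutoffFrac, paste(object@steepness, collapse = ", "),
    object@controlDepth, object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: genome %d bp, motif %d bp at %d, %d above-cutoff sites, %d tracks\n",
    genomeLength(object@series), object@truth$bTrue, object@truth$motifStart,
    nrow(object@truth$sites), length(object@series@tracks)))
})
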