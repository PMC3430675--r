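#' FrequencyTrack: per-position fragment coverage for one sequenced cycle
#'
#' One count per genome position, recording how many (extended) library
#' fragments from one sequenced afSELEX-seq cycle cover that position.
#' Cycle 1 is the unselected control library.
#'
#' @slot counts Numeric vector, one non-negative value per genome position.
#' @slot cycle Integer cycle index (1 = unselected control).
#' @slot nReads Integer number of aligned reads that built the track, or
#'   `NA` for synthetic tracks not built from reads.
#'
#' @seealso [buildTrack()], [CycleSeries-class]
#' @export
setClass("FrequencyTrack",
  representation(counts = "numeric", cycle = "integer", nReads = "integer"),
  prototype(counts = numeric(0), cycle = 1L, nReads = NA_integer_)
)

setValidity("FrequencyTrack", function(object) {
  if (length(object@counts) < 1L) return("counts must be non-empty")
  if (anyNA(object@counts) || any(object@counts < 0))
    return("counts must be non-negative and non-missing")
  if (length(object@cycle) != 1L || is.na(object@cycle) || object@cycle < 1L)
    return("cycle must be a single integer >= 1")
  if (length(object@nReads) != 1L)
    return("nReads must be a single integer (possibly NA)")
  TRUE
})

#' CycleSeries: ordered frequency tracks across afSELEX-seq cycles
#'
#' Holds one [FrequencyTrack-class] per sequenced cycle, ordered
#' control-first, plus the estimated mean library fragment length that
#' drives window sizes and length prediction.
#'
#' @slot tracks List of [FrequencyTrack-class] objects over the same genome,
#'   ordered by cycle; the first is the unselected control.
#' @slot fragmentLength Integer, estimated mean fragment length (bp) of a
#'   library member.
#'
#' @seealso [buildCycleSeries()], [callPeaks()]
#' @export
setClass("CycleSeries",
  representation(tracks = "list", fragmentLength = "integer")
)

setValidity("CycleSeries", function(object) {
  tr <- object@tracks
  if (length(tr) < 2L)
    return("need at least 2 tracks (control + >= 1 enrichment cycle)")
  if (!all(vapply(tr, is, logical(1), "FrequencyTrack")))
    return("all tracks must be FrequencyTrack objects")
  lens <- vapply(tr, function(t) length(t@counts), integer(1))
  if (length(unique(lens)) != 1L)
    return("all tracks must cover the same genome length")
  cyc <- vapply(tr, function(t) t@cycle, integer(1))
  if (is.unsorted(cyc, strictly = TRUE))
    return("track cycle indices must be strictly increasing")
  nr <- vapply(tr, function(t) t@nReads, integer(1))
  if (!anyNA(nr) && length(unique(nr)) != 1L)
    return("all tracks must be built from the same number of reads")
  if (length(object@fragmentLength) != 1L || is.na(object@fragmentLength) ||
      object@fragmentLength < 1L)
    return("fragmentLength must be a single integer >= 1")
  TRUE
})

#' PeakCallConfig: parameters of the sliding-window peak caller
#'
#' @slot fragmentLength Integer, estimated mean library fragment length L
#'   (bp); the scan window is 2L wide and peak spacing is L.
#' @slot statRange Integer radius (bp) of the window over which control-cycle
#'   mean and SD are computed around each candidate apex.
#' @slot minApex Numeric floor on the calling threshold, for degenerate
#'   (all-zero) control windows.
#' @slot sdMultiplier Numeric number of control SDs above the control mean a
#'   maximum must exceed (default 2, the 95% band).
#'
#' @seealso [peakCallConfig()], [callPeaks()]
#' @export
setClass("PeakCallConfig",
  representation(fragmentLength = "integer", statRange = "integer",
                 minApex = "numeric", sdMultiplier = "numeric")
)

setValidity("PeakCallConfig", function(object) {
  if (object@fragmentLength < 1L) return("fragmentLength must be >= 1")
  if (object@statRange < object@fragmentLength)
    return("statRange must be >= fragmentLength")
  if (object@sdMultiplier <= 0) return("sdMultiplier must be > 0")
  if (object@minApex < 0) return("minApex must be >= 0")
  TRUE
})

#' ScoringWeights: per-transition weights for enrichment scoring
#'
#' One positive weight per cycle transition (control to cycle 2, cycle 2 to
#' cycle 3, ...). A peak's score is the sum of weights over transitions in
#' which its apex frequency enriched. Later-round weights should be set
#' proportional to the bulk affinity of the corresponding library so that
#' enrichment under stronger competition counts more.
#'
#' @slot w Numeric vector of positive weights, one per transition.
#' @slot enrichFactor Numeric minimal fold-change for a transition to count
#'   as enrichment (1 = strictly greater).
#'
#' @seealso [scoringWeights()], [gradePeaks()]
#' @export
setClass("ScoringWeights",
  representation(w = "numeric", enrichFactor = "numeric")
)

setValidity("ScoringWeights", function(object) {
  if (length(object@w) < 1L || any(object@w <= 0) || anyNA(object@w))
    return("weights must be positive")
  if (length(object@enrichFactor) != 1L || object@enrichFactor <= 0)
    return("enrichFactor must be a single positive number")
  TRUE
})

#' ZeroOrderModel: single-base background frequencies
#'
#' A zero-order Markov model of base composition (one probability per base
#' A, C, G, T), as consumed by motif discovery tools as a background model.
#'
#' @slot p Named numeric vector of probabilities for A, C, G, T, summing
#'   to 1.
#'
#' @seealso [zeroOrderModel()], [writeBackground()]
#' @export
setClass("ZeroOrderModel", representation(p = "numeric"))

setValidity("ZeroOrderModel", function(object) {
  if (!identical(names(object@p), c("A", "C", "G", "T")))
    return("p must be named A, C, G, T")
  if (any(object@p < 0)) return("probabilities must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-5) return("probabilities must sum to 1")
  TRUE
})

#' SpoofSet: random background pseudo-peaks
#'
#' Randomly placed pseudo-peak positions and their genomic sequences, used
#' to build null base-composition models for motif discovery.
#'
#' @slot positions Integer vector of 1-based genome positions (window
#'   centers).
#' @slot seqRange Integer width (bp) of each extracted sequence.
#' @slot seed Integer seed the positions were drawn under.
#' @slot sequences Character vector of extracted sequences.
#'
#' @seealso [generateSpoofs()]
#' @export
setClass("SpoofSet",
  representation(positions = "integer", seqRange = "integer",
                 seed = "integer", sequences = "character")
)

setValidity("SpoofSet", function(object) {
  if (length(object@positions) != length(object@sequences))
    return("positions and sequences must have equal length")
  if (any(nchar(object@sequences) != object@seqRange))
    return("all sequences must have length seqRange")
  TRUE
})

#' SimilarityModel: positional weight matrix with a scaling factor
#'
#' A per-position base-probability matrix M (4 rows A, C, G, T; one column
#' per motif position) plus a scaling factor A. The similarity of an n-mer S
#' to the model is `A * sum_i M[S[i], i]`.
#'
#' @slot matrix Numeric 4 x n matrix, rows named A, C, G, T, each column
#'   summing to 1.
#' @slot scale Positive scaling factor A.
#'
#' @seealso [similarityModel()], [similarityScore()]
#' @export
setClass("SimilarityModel",
  representation(matrix = "matrix", scale = "numeric")
)

setValidity("SimilarityModel", function(object) {
  M <- object@matrix
  if (!identical(rownames(M), c("A", "C", "G", "T")))
    return("matrix rows must be named A, C, G, T")
  if (ncol(M) < 1L) return("matrix must have >= 1 position")
  if (any(M < 0)) return("matrix entries must be non-negative")
  if (any(abs(colSums(M) - 1) > 1e-9))
    return("each matrix column must sum to 1")
  if (length(object@scale) != 1L || object@scale <= 0)
    return("scale must be a single positive number")
  TRUE
})

#' SimConfig: configuration of the synthetic afSELEX-seq simulator
#'
#' @slot genomeSize Numeric genome length (bp).
#' @slot motifLenRange Integer length-2 vector, motif length drawn uniformly
#'   from this range (bp).
#' @slot nCycles Integer number of enrichment cycles (the control is extra).
#' @slot totalReads Numeric per-cycle read total to which each enrichment
#'   track's coverage mass (`totalReads * fragmentLength`) is normalized.
#' @slot fragmentLength Integer mean library fragment length (bp).
#' @slot cutoffFrac Numeric in (0,1); sites scoring below this fraction of
#'   the maximum similarity do not enrich at all.
#' @slot steepness Numeric per-cycle exponential steepness, strictly
#'   increasing across cycles.
#' @slot controlDepth Numeric mean coverage of the unselected control track.
#' @slot seed Integer seed.
#'
#' @seealso [simConfig()], [simulateDataset()]
#' @export
setClass("SimConfig",
  representation(genomeSize = "numeric", motifLenRange = "integer",
                 nCycles = "integer", totalReads = "numeric",
                 fragmentLength = "integer", cutoffFrac = "numeric",
                 steepness = "numeric", controlDepth = "numeric",
                 seed = "integer")
)

setValidity("SimConfig", function(object) {
  if (length(object@motifLenRange) != 2L ||
      object@motifLenRange[1] > object@motifLenRange[2] ||
      object@motifLenRange[1] < 1L)
    return("motifLenRange must be an increasing pair of positive lengths")
  if (object@genomeSize <= 2 * object@motifLenRange[2])
    return("genomeSize must exceed twice the maximum motif length")
  if (object@nCycles < 1L) return("need >= 1 enrichment cycle")
  if (length(object@steepness) != object@nCycles)
    return("steepness must have one value per enrichment cycle")
  if (is.unsorted(object@steepness, strictly = TRUE))
    return("steepness must be strictly increasing across cycles")
  if (object@cutoffFrac <= 0 || object@cutoffFrac >= 1)
    return("cutoffFrac must be in (0, 1)")
  if (object@totalReads <= 0) return("totalReads must be positive")
  if (object@fragmentLength < 1L) return("fragmentLength must be >= 1")
  if (object@controlDepth < 0) return("controlDepth must be >= 0")
  TRUE
})

#' SyntheticDataset: a simulated afSELEX-seq experiment with ground truth
#'
#' @slot genome A length-1 [Biostrings::DNAStringSet] holding the synthetic
#'   genome.
#' @slot series The simulated [CycleSeries-class] (control + enrichment
#'   tracks).
#' @slot truth List with elements `motif` (character), `bTrue` (integer
#'   motif length), `motifStart` (integer position of the planted motif) and
#'   `sites` (data.frame of above-cutoff site `position` and `similarity`).
#' @slot config The [SimConfig-class] the dataset was generated from.
#'
#' @seealso [simulateDataset()]
#' @export
setClass("SyntheticDataset",
  representation(genome = "DNAStringSet", series = "CycleSeries",
                 truth = "list", config = "SimConfig")
)

setValidity("SyntheticDataset", function(object) {
  if (length(object@genome) != 1L)
    return("genome must contain exactly one sequence")
  need <- c("motif", "bTrue", "motifStart", "sites")
  if (!all(need %in% names(object@truth)))
    return(paste("truth must contain:", paste(need, collapse = ", ")))
  if (length(object@series@tracks) != object@config@nCycles + 1L)
    return("series must have nCycles + 1 tracks")
  TRUE
})
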