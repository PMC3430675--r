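#' Generate random "spoof" background peaks
#'
#' Draws `n` uniform random positions on the genome (reproducibly for a
#' fixed seed), avoiding user-supplied excluded intervals -- by default the
#' supports of real called peaks -- and positions too close to the genome
#' ends for a full-length window, and extracts the sequence of width
#' `seqRange` centered on each. Spoof sequences supply a null
#' base-composition sample for motif-discovery counter-selection.
#'
#' @param genome Genome as [Biostrings::DNAStringSet], `DNAString` or
#'   character.
#' @param n Integer number of spoof peaks; sensibly matched to the real
#'   peak count.
#' @param seqRange Integer width (bp) of each spoof sequence; sensibly
#'   matched to the grading `seqRange`.
#' @param seed Integer seed.
#' @param exclude Optional intervals spoofs must not overlap: a graded/
#'   candidate peak data.frame (columns `left`, `right`) or an
#'   [IRanges::IRanges].
#' @param strict When `TRUE` (default), fewer admissible positions than `n`
#'   is an error; when `FALSE`, the spoof count is capped at the admissible
#'   count with a warning (useful on small or peak-dense genomes).
#' @return A [SpoofSet-class].
#' @export
generateSpoofs <- function(genome, n, seqRange, seed = 1L, exclude = NULL,
                           strict = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  g <- .genomeAsString(genome)
  G <- nchar(g)
  half <- (seqRange - 1L) %/% 2L
  rest <- seqRange - 1L - half
  if (G < seqRange) stop("genome shorter than seqRange")
  ok <- rep(TRUE, G)
  ok[seq_len(min(half, G))] <- FALSE
  if (rest > 0) ok[(G - rest + 1L):G] <- FALSE
  if (!is.null(exclude)) {
    if (is.data.frame(exclude))
      exclude <- IRanges::IRanges(exclude$left, exclude$right)
    # a window [c-half, c+rest] overlaps an excluded interval [a,b]
    # iff c lies in [a-rest, b+half]
    from <- pmax(BiocGenerics::start(exclude) - rest, 1L)
    to <- pmin(BiocGenerics::end(exclude) + half, G)
    for (i in seq_along(from)) ok[from[i]:to[i]] <- FALSE
  }
  allowed <- which(ok)
  if (length(allowed) < n) {
    if (strict || length(allowed) == 0L)
      stop("genome has only ", length(allowed),
           " admissible spoof positions; ", n, " requested")
    warning("capping spoof count at the ", length(allowed),
            " admissible positions (", n, " requested)")
    n <- length(allowed)
  }
  centers <- .withSeed(seed, sort(sample(allowed, n)))
  seqs <- substring(g, centers - half, centers + rest)
  new("SpoofSet", positions = as.integer(centers),
      seqRange = as.integer(seqRange), seed = as.integer(seed),
      sequences = seqs)
}

#' Zero-order Markov background model from sequences
#'
#' Single-base frequencies pooled over all input sequences; characters
#' other than A/C/G/T (e.g. N) are ignored.
#'
#' @param sequences Character vector of DNA sequences, or a
#'   [SpoofSet-class].
#' @return A [ZeroOrderModel-class].
#' @examples
#' zeroOrderModel(c("AAAA", "AACC"))  # A 0.75, C 0.25
#' @export
zeroOrderModel <- function(sequences) {
  if (is(sequences, "SpoofSet")) sequences <- sequences@sequences
  if (length(sequences) < 1L) stop("need at least one sequence")
  chars <- strsplit(toupper(paste(sequences, collapse = "")), "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b),
                   numeric(1))
  if (sum(counts) == 0) stop("sequences contain no countable A/C/G/T bases")
  new("ZeroOrderModel", p = counts / sum(counts))
}

#' Write a zero-order background model file
#'
#' One line per base, `<base> <probability>` with six decimals -- the
#' background-file dialect consumed by motif discovery tools
#' (e.g. as a `-bfile`).
#'
#' @param model A [ZeroOrderModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBackground <- function(model, path) {
  writeLines(sprintf("%s %.6f", names(model@p), model@p), path)
  invisible(path)
}

#' Read a zero-order background model file
#'
#' @param path Path written by [writeBackground()].
#' @return A [ZeroOrderModel-class].
#' @export
readBackground <- function(path) {
  lines <- strsplit(readLines(path), " +")
  bases <- vapply(lines, `[[`, "", 1L)
  p <- as.numeric(vapply(lines, `[[`, "", 2L))
  names(p) <- bases
  new("ZeroOrderModel", p = p[c("A", "C", "G", "T")])
}
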