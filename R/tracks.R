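#' Construct a FrequencyTrack
#'
#' @param counts Numeric vector of non-negative per-position counts.
#' @param cycle Integer cycle index (1 = unselected control).
#' @param nReads Integer number of reads the track was built from, or `NA`.
#' @return A [FrequencyTrack-class] object.
#' @examples
#' FrequencyTrack(c(0, 2, 3, 2, 0), cycle = 2L, nReads = 3L)
#' @export
FrequencyTrack <- function(counts, cycle = 1L, nReads = NA_integer_) {
  new("FrequencyTrack", counts = as.numeric(counts),
      cycle = as.integer(cycle), nReads = as.integer(nReads))
}

#' Construct a CycleSeries
#'
#' @param tracks List of [FrequencyTrack-class] objects, control first.
#' @param fragmentLength Integer mean library fragment length (bp).
#' @return A [CycleSeries-class] object.
#' @export
CycleSeries <- function(tracks, fragmentLength) {
  new("CycleSeries", tracks = tracks,
      fragmentLength = as.integer(fragmentLength))
}

#' Read a single-sequence genome FASTA
#'
#' @param path Path to a FASTA file holding exactly one sequence.
#' @return A length-1 [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) != 1L)
    stop("genome FASTA must contain exactly one sequence; also found: ",
         paste(names(genome)[-1], collapse = ", "))
  genome
}

#' Read aligned reads from a SAM file
#'
#' Parses mapped primary alignments from a SAM file produced by any aligner.
#' Unmapped (flag 0x4), secondary (0x100) and supplementary (0x800) records
#' are skipped. The reference span of each alignment is computed from its
#' CIGAR, so indels and skips are handled. Alignments extending beyond
#' `genomeLength` are rejected with a warning reporting their number.
#'
#' @param path Path to a SAM file.
#' @param genomeLength Integer length of the (single) target sequence.
#' @return A data.frame with one row per retained alignment and columns
#'   `start` (1-based leftmost reference position), `width` (reference span,
#'   bp) and `strand` (`"+"`/`"-"`).
#' @seealso [readBlastTabular()], [buildTrack()]
#' @export
readSAM <- function(path, genomeLength) {
  lines <- readLines(path)
  body <- !startsWith(lines, "@")
  recs <- lines[body]
  lineNo <- which(body)
  if (length(recs) == 0L)
    return(data.frame(start = integer(0), width = integer(0),
                      strand = character(0)))

  fields <- strsplit(recs, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad))
    stop("malformed SAM record (fewer than 11 fields) at line ",
         lineNo[bad[1]], " of ", path)

  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  cigar <- vapply(fields, `[[`, "", 6L)
  bad <- which(is.na(flag) | is.na(pos))
  if (length(bad))
    stop("unparseable FLAG/POS in SAM record at line ", lineNo[bad[1]],
         " of ", path)

  keep <- bitwAnd(flag, 0x4L) == 0L &   # mapped
    bitwAnd(flag, 0x100L) == 0L &       # primary
    bitwAnd(flag, 0x800L) == 0L         # non-supplementary
  flag <- flag[keep]; pos <- pos[keep]; cigar <- cigar[keep]
  lineNo <- lineNo[keep]

  bad <- which(cigar == "*" | pos < 1L)
  if (length(bad))
    stop("mapped SAM record without CIGAR/position at line ", lineNo[bad[1]],
         " of ", path)

  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  strand <- ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+")

  off <- pos + width - 1L > genomeLength
  if (any(off)) {
    warning(sum(off), " alignment(s) extend beyond the genome (",
            genomeLength, " bp) and were rejected")
    pos <- pos[!off]; width <- width[!off]; strand <- strand[!off]
  }
  data.frame(start = pos, width = width, strand = strand)
}

#' Read aligned reads from BLASTn tabular output
#'
#' Parses the 12-column tabular dialect (`-outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). Only
#' the best-scoring hit per query (highest bitscore) is kept. A hit with
#' `send < sstart` is a minus-strand alignment.
#'
#' @param path Path to a BLASTn tabular file.
#' @return A data.frame with columns `start`, `width`, `strand` as in
#'   [readSAM()].
#' @export
readBlastTabular <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L)
    stop("BLAST tabular input must have 12 columns (-outfmt 6); got ",
         ncol(tab), " in ", path)
  names(tab) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")
  tab <- tab[order(-tab$bitscore), , drop = FALSE]
  tab <- tab[!duplicated(tab$qseqid), , drop = FALSE]
  data.frame(
    start = pmin(tab$sstart, tab$send),
    width = abs(tab$send - tab$sstart) + 1L,
    strand = ifelse(tab$send < tab$sstart, "-", "+"),
    row.names = NULL)
}

#' Equalize read counts across cycles by seeded subsampling
#'
#' afSELEX-seq cycles are sequenced to different depths; downstream
#' comparisons require every cycle to contribute the same number of aligned
#' reads. Reads are drawn uniformly without replacement, reproducibly for a
#' fixed seed, and invariantly to the input row order (each cycle is sorted
#' into a canonical order before sampling).
#'
#' @param readsByCycle List of read data.frames (as from [readSAM()]),
#'   control first.
#' @param n Number of reads to keep per cycle; defaults to the smallest
#'   cycle's read count.
#' @param seed Integer seed.
#' @return A list of read data.frames, each with exactly `n` rows.
#' @export
subsampleReads <- function(readsByCycle, n = NULL, seed = 1L) {
  counts <- vapply(readsByCycle, nrow, integer(1))
  if (is.null(n)) n <- min(counts)
  n <- as.integer(n)
  if (any(counts < n)) {
    lim <- which.min(counts)
    stop("cannot draw ", n, " reads: cycle ", lim, " has only ",
         counts[lim], " aligned reads")
  }
  canon <- lapply(readsByCycle, function(r) {
    r[order(r$start, r$width, r$strand), , drop = FALSE]
  })
  .withSeed(seed, lapply(canon, function(r) {
    out <- r[sort(sample.int(nrow(r), n)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }))
}

#' Build a fragment-coverage frequency track from aligned reads
#'
#' Each read contributes +1 to every position of its occupied interval: the
#' aligned span, extended 3'-ward on its strand to the mean library fragment
#' length `fragmentLength` when the aligned span is shorter (sequencing
#' reads only one end of the fragment), and truncated at the genome ends.
#' The track total therefore equals the summed occupied-interval lengths.
#'
#' @param reads Read data.frame (`start`, `width`, `strand`).
#' @param genomeLength Integer genome length (bp).
#' @param fragmentLength Integer mean library fragment length L (bp).
#' @param cycle Integer cycle index stored in the track.
#' @return A [FrequencyTrack-class].
#' @examples
#' reads <- data.frame(start = 11, width = 50, strand = "+")
#' tr <- buildTrack(reads, genomeLength = 100, fragmentLength = 50)
#' sum(trackCounts(tr))  # 50
#' @export
buildTrack <- function(reads, genomeLength, fragmentLength, cycle = 1L) {
  genomeLength <- as.integer(genomeLength)
  if (fragmentLength < 1L) stop("fragmentLength must be >= 1")
  if (nrow(reads) == 0L)
    return(FrequencyTrack(numeric(genomeLength), cycle, 0L))
  ext <- pmax(reads$width, as.integer(fragmentLength))
  plus <- reads$strand != "-"
  from <- ifelse(plus, reads$start, reads$start + reads$width - ext)
  to <- ifelse(plus, reads$start + ext - 1L, reads$start + reads$width - 1L)
  from <- pmax(from, 1L)
  to <- pmin(to, genomeLength)
  cov <- IRanges::coverage(IRanges::IRanges(from, to), width = genomeLength)
  FrequencyTrack(as.numeric(cov), cycle, nrow(reads))
}

#' Build an equalized CycleSeries from per-cycle reads
#'
#' Convenience composition of [subsampleReads()] and [buildTrack()]:
#' subsamples every cycle to the same read count, then builds one coverage
#' track per cycle (control first).
#'
#' @inheritParams subsampleReads
#' @inheritParams buildTrack
#' @return A [CycleSeries-class].
#' @export
buildCycleSeries <- function(readsByCycle, genomeLength, fragmentLength,
                             n = NULL, seed = 1L) {
  sub <- subsampleReads(readsByCycle, n = n, seed = seed)
  trk <- lapply(seq_along(sub), function(i) {
    buildTrack(sub[[i]], genomeLength, fragmentLength, cycle = i)
  })
  CycleSeries(trk, fragmentLength)
}
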