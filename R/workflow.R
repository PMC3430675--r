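#' Build a CycleSeries from a genome FASTA and per-cycle alignment files
#'
#' Reads one alignment file per sequenced cycle (control first), SAM or
#' BLASTn 12-column tabular, equalizes read counts by seeded subsampling
#' and builds coverage tracks.
#'
#' @param genomePath Path to the single-sequence genome FASTA.
#' @param cyclePaths Character vector of alignment file paths in cycle
#'   order, control first (>= 2 files).
#' @param fragmentLength Integer mean library fragment length (bp).
#' @param format `"auto"` (by extension: `.sam` vs anything else),
#'   `"sam"` or `"blast"`.
#' @param n Reads per cycle after subsampling (default: smallest cycle).
#' @param seed Integer subsampling seed.
#' @return A list with `series` (a [CycleSeries-class]) and `genome` (a
#'   length-1 `DNAStringSet`).
#' @export
readCycleSeries <- function(genomePath, cyclePaths, fragmentLength,
                            format = c("auto", "sam", "blast"), n = NULL,
                            seed = 1L) {
  format <- match.arg(format)
  if (length(cyclePaths) < 2L)
    stop("need >= 2 cycle alignment files (control + enrichment)")
  missing <- cyclePaths[!file.exists(cyclePaths)]
  if (length(missing))
    stop("alignment file(s) not found: ", paste(missing, collapse = ", "))
  genome <- readGenomeFasta(genomePath)
  G <- Biostrings::width(genome)[1]
  readsByCycle <- lapply(cyclePaths, function(p) {
    fmt <- if (format != "auto") format
           else if (grepl("\\.sam$", p, ignore.case = TRUE)) "sam"
           else "blast"
    if (fmt == "sam") readSAM(p, G) else readBlastTabular(p)
  })
  empty <- which(vapply(readsByCycle, nrow, integer(1)) == 0L)
  if (length(empty))
    stop("cycle file with no usable alignments: ", cyclePaths[empty[1]])
  list(series = buildCycleSeries(readsByCycle, G, fragmentLength,
                                 n = n, seed = seed),
       genome = genome)
}

#' Run the full peak analysis and write all reports
#'
#' Calls peaks on the final enrichment cycle, grades them across cycles,
#' generates spoof background peaks and a zero-order background model, and
#' (when `outPrefix` is given) writes the tab-delimited hierarchical peak
#' report, peak FASTA, BED of peak supports, spoof FASTA and background
#' model file. Progress and the summary (peaks per class, predicted
#' binding-site length over best-class peaks as mean and SD) are reported
#' via `message()`, never mixed into the report files. All outputs are
#' byte-identical under a fixed seed and configuration.
#'
#' @param series A [CycleSeries-class] (control first).
#' @param genome The matching genome ([Biostrings::DNAStringSet],
#'   `DNAString` or character); required for sequence, spoof and background
#'   output.
#' @param config A [PeakCallConfig-class]; defaults to
#'   `peakCallConfig(fragmentLength(series))`.
#' @param weights A [ScoringWeights-class]; defaults to doubling weights.
#' @param seqRange Reported peak-sequence length (bp, default 200).
#' @param spoofN Number of spoof peaks (default: one per called peak).
#' @param seed Integer seed for spoof placement.
#' @param outPrefix Optional path prefix for report files
#'   (`<prefix>_peaks.tsv`, `_peaks.fasta`, `_peaks.bed`, `_spoofs.fasta`,
#'   `_background.txt`).
#' @return Invisibly, a list with `peaks` (graded data.frame), `spoofs`,
#'   `background` and `summary`.
#' @export
runAnalysis <- function(series, genome = NULL,
                        config = peakCallConfig(fragmentLength(series)),
                        weights = scoringWeights(nCycles(series) - 1L),
                        seqRange = 200L, spoofN = NULL, seed = 1L,
                        outPrefix = NULL) {
  if (!is.null(genome)) {
    G <- nchar(.genomeAsString(genome))
    if (G != genomeLength(series))
      stop("genome length (", G, ") does not match track length (",
           genomeLength(series), ")")
  }
  candidates <- callPeaks(series, config)
  graded <- gradePeaks(candidates, series, weights = weights,
                       genome = genome, seqRange = seqRange)

  spoofs <- NULL
  background <- NULL
  if (nrow(graded) == 0L) {
    warning("no peaks called: final cycle never exceeds the control ",
            "threshold")
  } else if (!is.null(genome)) {
    spoofs <- tryCatch(
      generateSpoofs(genome, n = if (is.null(spoofN)) nrow(graded)
                                 else spoofN,
                     seqRange = seqRange, seed = seed,
                     exclude = graded, strict = FALSE),
      error = function(e) {
        warning("skipping spoof/background output: ", conditionMessage(e))
        NULL
      })
    if (!is.null(spoofs)) background <- zeroOrderModel(spoofs)
  }

  best <- graded$predictedLength[graded$class == 1L]
  summary <- list(
    nPeaks = nrow(graded),
    classCounts = if (nrow(graded)) table(graded$class) else table(integer(0)),
    bestLengthMean = if (length(best)) mean(best) else NA_real_,
    bestLengthSD = if (length(best) > 1L) stats::sd(best) else
                   if (length(best) == 1L) 0 else NA_real_)
  message(sprintf("called %d peak(s); per class: %s", summary$nPeaks,
                  if (summary$nPeaks)
                    paste(sprintf("class %s: %d",
                                  names(summary$classCounts),
                                  as.integer(summary$classCounts)),
                          collapse = ", ")
                  else "none"))
  if (summary$nPeaks)
    message(sprintf(
      "predicted binding-site length over best-class peaks: %.2f bp +/- SD %.2f bp",
      summary$bestLengthMean, summary$bestLengthSD))

  if (!is.null(outPrefix)) {
    dir.create(dirname(outPrefix), recursive = TRUE, showWarnings = FALSE)
    writePeakReport(graded, paste0(outPrefix, "_peaks.tsv"))
    if (nrow(graded) > 0L && !is.null(genome)) {
      writePeakFasta(graded, paste0(outPrefix, "_peaks.fasta"))
      writePeakBed(graded, paste0(outPrefix, "_peaks.bed"))
    }
    if (!is.null(spoofs)) {
      writeSpoofFasta(spoofs, paste0(outPrefix, "_spoofs.fasta"))
      writeBackground(background, paste0(outPrefix, "_background.txt"))
    }
  }
  invisible(list(peaks = graded, spoofs = spoofs, background = background,
                 summary = summary))
}

#' Write spoof sequences as FASTA
#'
#' @param spoofs A [SpoofSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSpoofFasta <- function(spoofs, path) {
  seqs <- Biostrings::DNAStringSet(spoofs@sequences)
  names(seqs) <- sprintf("spoof%d|%d", seq_along(spoofs@positions),
                         spoofs@positions)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the genome FASTA (`genome.fa`), one two-column TSV per cycle
#' (`cycle_<i>.tsv`: position, count), the truth/site table (`sites.tsv`)
#' and a key-value manifest (`manifest.tsv`) holding the motif, its true
#' length and position, and the full generating configuration. Outputs are
#' byte-identical for identical datasets.
#'
#' @param dataset A [SyntheticDataset-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(dataset@genome, file.path(dir, "genome.fa"))
  cfg <- dataset@config
  for (i in seq_along(tracks(dataset@series))) {
    cnt <- trackCounts(dataset@series, i)
    write.table(data.frame(position = seq_along(cnt), count = cnt),
                file.path(dir, sprintf("cycle_%d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- c(
    motif = dataset@truth$motif,
    bTrue = dataset@truth$bTrue,
    motifStart = dataset@truth$motifStart,
    genomeSize = cfg@genomeSize,
    motifLenMin = cfg@motifLenRange[1], motifLenMax = cfg@motifLenRange[2],
    nCycles = cfg@nCycles, totalReads = cfg@totalReads,
    fragmentLength = cfg@fragmentLength, cutoffFrac = cfg@cutoffFrac,
    steepness = paste(cfg@steepness, collapse = ","),
    controlDepth = cfg@controlDepth, seed = cfg@seed)
  write.table(data.frame(key = names(manifest), value = unname(manifest)),
              file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset@truth$sites, file.path(dir, "sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic dataset back from a directory
#'
#' @param dir Directory written by [writeDataset()].
#' @return A [SyntheticDataset-class].
#' @export
readDataset <- function(dir) {
  manPath <- file.path(dir, "manifest.tsv")
  if (!file.exists(manPath)) stop("no manifest.tsv in ", dir)
  man <- read.delim(manPath, stringsAsFactors = FALSE)
  val <- stats::setNames(as.character(man$value), man$key)
  cfg <- simConfig(
    genomeSize = as.numeric(val["genomeSize"]),
    motifLenRange = as.integer(c(val["motifLenMin"], val["motifLenMax"])),
    nCycles = as.integer(val["nCycles"]),
    totalReads = as.numeric(val["totalReads"]),
    fragmentLength = as.integer(val["fragmentLength"]),
    cutoffFrac = as.numeric(val["cutoffFrac"]),
    steepness = as.numeric(strsplit(val["steepness"], ",")[[1]]),
    controlDepth = as.numeric(val["controlDepth"]),
    seed = as.integer(val["seed"]))
  genome <- readGenomeFasta(file.path(dir, "genome.fa"))
  trk <- lapply(seq_len(cfg@nCycles + 1L), function(i) {
    tab <- read.delim(file.path(dir, sprintf("cycle_%d.tsv", i)))
    FrequencyTrack(tab$count, cycle = i)
  })
  sites <- read.delim(file.path(dir, "sites.tsv"))
  new("SyntheticDataset", genome = genome,
      series = CycleSeries(trk, cfg@fragmentLength),
      truth = list(motif = unname(val["motif"]),
                   bTrue = as.integer(val["bTrue"]),
                   motifStart = as.integer(val["motifStart"]),
                   sites = sites),
      config = cfg)
}

#' Simulate a batch of datasets
#'
#' @param config Base [SimConfig-class]; each dataset reuses it with one of
#'   `seeds`.
#' @param seeds Integer vector of seeds, one dataset each.
#' @param dir Optional directory; when given, each dataset is written to
#'   `dir/dataset_<seed>` via [writeDataset()].
#' @return Invisibly, the list of [SyntheticDataset-class] objects (named
#'   by seed).
#' @export
simulateBatch <- function(config, seeds, dir = NULL) {
  datasets <- lapply(seeds, function(s) {
    cfg <- config
    cfg@seed <- as.integer(s)
    ds <- simulateDataset(cfg)
    if (!is.null(dir))
      writeDataset(ds, file.path(dir, sprintf("dataset_%d", s)))
    ds
  })
  names(datasets) <- as.character(seeds)
  invisible(datasets)
}

#' Binding-site length recovery statistics for one dataset
#'
#' Takes the `topN` most-enriched best-class peaks (report order: maximal
#' score, ties by area), computes mean and SD of their predicted
#' binding-site lengths, and tests whether the true motif length lies
#' within 1 and within 2 SDs of the mean. With a single qualifying peak
#' (SD 0) an exact match counts as within.
#'
#' @param graded Graded peak data.frame from [gradePeaks()].
#' @param bTrue True motif length (bp).
#' @param topN Number of best-class peaks to use (default 100; fewer if
#'   fewer exist).
#' @return List with `n`, `mean`, `sd`, `within1`, `within2`.
#' @export
recoveryStats <- function(graded, bTrue, topN = 100L) {
  best <- graded[graded$class == 1L, , drop = FALSE]
  best <- head(best, topN)  # report order = score desc, area desc
  if (nrow(best) == 0L)
    return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                within1 = FALSE, within2 = FALSE))
  preds <- best$predictedLength
  m <- mean(preds)
  s <- if (length(preds) > 1L) stats::sd(preds) else 0
  list(n = nrow(best), mean = m, sd = s,
       within1 = abs(bTrue - m) <= s + 1e-9,
       within2 = abs(bTrue - m) <= 2 * s + 1e-9)
}

#' Aggregate length-recovery accuracy over analyzed dataset directories
#'
#' Each directory must contain the truth manifest of [writeDataset()] and
#' the peak report written by [runAnalysis()] (prefix `run`, i.e.
#' `run_peaks.tsv`). Per dataset the true motif length, the mean and SD of
#' predicted lengths over the top `topN` best-class peaks and the
#' within-1-SD / within-2-SD indicators are reported, plus aggregate
#' percentages.
#'
#' @param dirs Character vector of dataset directories.
#' @param topN Best-class peaks per dataset (default 100).
#' @param reportName File name of the peak report inside each directory.
#' @return List with `perDataset` (data.frame) and `within1Pct`,
#'   `within2Pct` (percentages over datasets).
#' @export
validateRecovery <- function(dirs, topN = 100L,
                             reportName = "run_peaks.tsv") {
  rows <- lapply(dirs, function(d) {
    manPath <- file.path(d, "manifest.tsv")
    if (!file.exists(manPath)) stop("no manifest.tsv in ", d)
    man <- read.delim(manPath, stringsAsFactors = FALSE)
    bTrue <- as.integer(man$value[man$key == "bTrue"])
    repPath <- file.path(d, reportName)
    if (!file.exists(repPath)) stop("no peak report (", reportName,
                                    ") in ", d)
    graded <- read.delim(repPath, stringsAsFactors = FALSE)
    st <- recoveryStats(graded, bTrue, topN = topN)
    data.frame(dir = d, bTrue = bTrue, nBest = st$n,
               predictedMean = st$mean, predictedSD = st$sd,
               within1SD = st$within1, within2SD = st$within2)
  })
  per <- do.call(rbind, rows)
  list(perDataset = per,
       within1Pct = 100 * mean(per$within1SD),
       within2Pct = 100 * mean(per$within2SD))
}
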