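# Shared fixture builders; everything is generated in code at test time.

# Minimal SAM file over a single reference "chr" of the given length.
# `records` is a data.frame with qname, flag, pos, cigar.
writeSamFixture <- function(path, records, refLen = 1000L) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:chr\tLN:%d", refLen))
  body <- sprintf("%s\t%d\tchr\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  records$qname, records$flag, records$pos, records$cigar)
  writeLines(c(header, body), path)
  path
}

# 12-column BLAST -outfmt 6 rows.
writeBlastFixture <- function(path, rows) {
  lines <- sprintf("%s\tchr\t100.00\t%d\t0\t0\t1\t%d\t%d\t%d\t1e-20\t%.1f",
                   rows$qseqid, abs(rows$send - rows$sstart) + 1L,
                   abs(rows$send - rows$sstart) + 1L,
                   rows$sstart, rows$send, rows$bitscore)
  writeLines(lines, path)
  path
}

# A small series with well-separated triangular peaks that enrich in every
# cycle, over a flat control. Returns list(series, apexes).
makeTriangleSeries <- function(G = 2000L, L = 20L, apexes = c(300L, 900L, 1500L),
                               heights = c(60, 80, 100), controlLevel = 1) {
  bump <- function(track, apex, h) {
    w <- L
    x <- (apex - w):(apex + w)
    track[x] <- track[x] + h * (1 - abs(x - apex) / (w + 1))
    track
  }
  mk <- function(mult, cycle) {
    tr <- numeric(G)
    for (i in seq_along(apexes)) tr <- bump(tr, apexes[i], heights[i] * mult)
    FrequencyTrack(tr, cycle = cycle)
  }
  control <- FrequencyTrack(rep(controlLevel, G), cycle = 1L)
  series <- CycleSeries(list(control, mk(1, 2L), mk(2, 3L), mk(4, 4L)), L)
  list(series = series, apexes = apexes, heights = heights)
}

# Random DNA string.
randomGenome <- function(G, seed = 1L) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), G, replace = TRUE), collapse = ""))
}

# A small, quick simulated dataset reused across tests.
smallDataset <- local({
  cache <- new.env()
  function(seed = 5L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulateDataset(simConfig(
        genomeSize = 5e4, totalReads = 2e5, fragmentLength = 50L,
        motifLenRange = c(18L, 24L), seed = seed))
    }
    cache[[key]]
  }
})
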