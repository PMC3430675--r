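# Internal helpers shared across modules.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Coerce a genome given as DNAStringSet / DNAString / character to a single
# uppercase character string (plus its length).
.genomeAsString <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (length(genome) != 1L)
      stop("genome must contain exactly one sequence; got ", length(genome))
    genome <- as.character(genome[[1]])
  } else if (is(genome, "DNAString")) {
    genome <- as.character(genome)
  } else if (is.character(genome)) {
    if (length(genome) != 1L)
      stop("genome must be a single sequence")
  } else {
    stop("genome must be a DNAStringSet, DNAString or character string")
  }
  toupper(genome)
}

# Counts from a FrequencyTrack or bare numeric vector.
.asCounts <- function(x) {
  if (is(x, "FrequencyTrack")) x@counts else as.numeric(x)
}

# 2 * qnorm(0.995): full width, in SDs, of the central 99% of a Gaussian.
.CENTRAL99 <- 2 * qnorm(0.995)
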