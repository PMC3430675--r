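# Independent brute-force oracles for the peak-calling operations.

# Sliding-window maximum scan, written as a plain double loop: position p
# qualifies iff it strictly exceeds the left half-window, weakly exceeds
# the right half-window and strictly exceeds the window minimum.
bruteMaxima <- function(x, L) {
  G <- length(x)
  out <- integer(0)
  for (p in seq_len(G)) {
    win <- max(1, p - L):min(G, p + L)
    lft <- win[win < p]; rgt <- win[win > p]
    if ((length(lft) == 0 || x[p] > max(x[lft])) &&
        (length(rgt) == 0 || x[p] >= max(x[rgt])) &&
        x[p] > min(x[win]))
      out <- c(out, p)
  }
  out
}

# Pairwise re-application of the delimiting rules as a plain left-to-right
# pass: closer than L merges (higher apex survives) unless the valley drops
# below 50% of the smaller apex or the apexes are within 75% of each other.
bruteDelimit <- function(maxima, x, L) {
  keep <- integer(0)
  cur <- maxima[1]
  for (m in maxima[-1]) {
    sep <- m - cur >= L
    if (!sep) {
      small <- min(x[cur], x[m]); big <- max(x[cur], x[m])
      deepValley <- min(x[cur:m]) < 0.5 * small
      similar <- small >= 0.75 * big
      sep <- deepValley || similar
    }
    if (sep) { keep <- c(keep, cur); cur <- m }
    else cur <- if (x[m] > x[cur]) m else cur
  }
  c(keep, cur)
}
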