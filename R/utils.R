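# Fold a proposed position back into [0, L] (billiard reflection; handles
# steps longer than the tube by repeated folding via the 2L-periodic map).
reflect_position <- function(y, L) {
  if (y >= 0 && y <= L) return(y)
  period <- 2 * L
  y <- y %% period
  if (y > L) y <- period - y
  y
}

# Right-aligned rolling mean with partial windows at the start: element i
# is the mean of x[max(1, i - w + 1) .. i].
rolling_mean_right <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

# Deterministic per-fly substream seed: a fixed counter scheme keyed by the
# fly's design-cell index and within-cell replicate, so growing a cohort
# never reshuffles previously generated flies. Kept below 2^31.
fly_substream_seed <- function(master_seed, cell_index, replicate) {
  counter <- (cell_index - 1) * 10000 + replicate
  as.integer((as.numeric(master_seed) * 1000003 + counter) %% 2147483647)
}
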