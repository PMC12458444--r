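# Shared fixtures, all generated in code.

toy_design <- function(L = 65, dt = 1, stim = 3600, dur = 3720) {
  assay_design(tube_length_mm = L, dt_s = dt, stimulus_times_s = stim,
               recording_duration_s = dur)
}

# trajectory with prescribed positions; tube sized to fit
make_traj <- function(positions, dt = 1, fly_id = "f1",
                      L = max(max(positions), 1)) {
  fly_trajectory(fly_id, (seq_along(positions) - 1) * dt, positions,
                 toy_design(L = L, dt = dt))
}

# trajectory whose derived speeds equal `speeds` (speeds[1] must be 0):
# monotone path on a long tube
traj_from_speeds <- function(speeds, dt = 1, fly_id = "f1") {
  stopifnot(speeds[1] == 0)
  pos <- cumsum(speeds * dt)
  make_traj(pos, dt = dt, fly_id = fly_id, L = max(pos) + 1)
}

# balanced toy metadata: n flies per genotype x sex x temperature x block
toy_metadata <- function(n = 1, temps = c(20, 25, 30), blocks = c("B1", "B2")) {
  g <- expand.grid(genotype = c("STD", "HET", "INV"), sex = c("F", "M"),
                   temperature_c = temps, experiment_block = blocks,
                   rep = seq_len(n), stringsAsFactors = FALSE)
  data.frame(fly_id = sprintf("fly%04d", seq_len(nrow(g))),
             genotype = g$genotype, sex = g$sex,
             temperature_c = g$temperature_c,
             experiment_block = g$experiment_block,
             cross_id = "c1", stringsAsFactors = FALSE)
}

# independent run-length scanner used as the bout-detection oracle
brute_force_bouts <- function(active, min_len = 5) {
  inact <- !active
  n <- length(inact)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (inact[i]) {
      j <- i
      while (j < n && inact[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len)
        out[[length(out) + 1L]] <- data.frame(start_s = (i - 1L) * 60,
                                              end_s = j * 60,
                                              duration_min = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_min = numeric(0))
}
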