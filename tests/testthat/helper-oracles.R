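# Independent brute-force oracles for the windowed features, written as
# explicit loops so they share no code path with the package implementations.

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

oracle_wl <- function(x) {
  s <- 0
  for (k in seq_len(length(x) - 1L)) s <- s + abs(x[k + 1L] - x[k])
  s
}

oracle_zc <- function(x, thr) {
  n <- 0L
  for (k in seq_len(length(x) - 1L)) {
    if (x[k] * x[k + 1L] < 0 && abs(x[k] - x[k + 1L]) >= thr) n <- n + 1L
  }
  n
}

oracle_ssc <- function(x, thr) {
  n <- 0L
  for (k in 2:(length(x) - 1L)) {
    p <- (x[k] - x[k - 1L]) * (x[k] - x[k + 1L])
    if (p > 0 && p >= thr) n <- n + 1L
  }
  n
}

oracle_spike_count <- function(spikes0, start0, end0) {
  n <- 0L
  for (s in spikes0) if (s >= start0 && s < end0) n <- n + 1L
  n
}

# Small session used across files: 4x4 grid, 1 s ramps, low rate keeps it fast.
small_session <- function(seed = 42, ...) {
  args <- list(ramp_duration = 1, n_trials = 3, units_per_pool = 10,
               grid_shape = c(4L, 4L), sample_rate = 1024, rest_duration = 1.5,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_session, args)
}
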