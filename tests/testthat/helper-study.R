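# Shared heavyweight study computations, evaluated once per test run.

.study_cache <- new.env(parent = emptyenv())

# Ten single-speed sessions with decomposition-error corruption (20% missed
# discharges, 2/s false positives, 70% of units detected with a
# high-threshold sampling bias), each evaluated with repeated three-fold
# leave-one-ramp-out cross-validation for the TD, AM2 and PROPOSED sets.
corrupted_study <- function() {
  if (!is.null(.study_cache$corrupted)) return(.study_cache$corrupted)
  corr <- corruption_spec(miss_rate = 0.2, false_positive_rate = 2,
                          detected_fraction = 0.7, high_threshold_bias = 1)
  rows <- NULL
  for (seed in 1:10) {
    s <- sim_session(ramp_duration = 1, corruption = corr, seed = seed)
    rep <- run_comparison(s, kinds = c("TD", "AM2", "PROPOSED"),
                          repeats = 2, seed = seed + 500)
    sm <- summary(rep)
    sm$seed <- seed
    rows <- rbind(rows, sm)
    rm(s, rep); gc(FALSE)
  }
  .study_cache$corrupted <- rows
  rows
}

study_means <- function(rows, kind) {
  vapply(split(rows, rows$seed), function(g)
    g$mean_r2[g$kind == kind], 0)
}
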