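test_that("triangular cues start and end at neutral with the cued amplitude", {
  fs <- 2048
  prof <- cue_profile(1, ramp_duration = 1, n_trials = 3, rom = 60,
                     rest_duration = 2, sample_rate = fs)
  cue <- generate_cue(prof)
  ang <- cue$angles
  expect_equal(max(ang[1, ]), 60)
  expect_equal(min(ang[1, ]), -60)
  expect_equal(ang[1, 1], 0)
  expect_equal(ang[1, ncol(ang)], 0)
  expect_true(all(ang[2:3, ] == 0))

  # constant slope magnitude inside each ramp episode
  seg <- attr(cue, "segmentation")
  expect_equal(nrow(seg), 6L) # 3 trials x 2 directions
  for (k in seq_len(nrow(seg))) {
    ep <- ang[1, (seg$start_sample[k] + 1):(seg$end_sample[k])]
    slopes <- abs(diff(ep))
    expect_lt(diff(range(slopes)), 1e-9)
  }
})

test_that("episode sample counts follow the closed-form triangular schedule", {
  fs <- 2048
  cue <- generate_cue(cue_profile(2, ramp_duration = 5, n_trials = 1,
                                  sample_rate = fs))
  seg <- attr(cue, "segmentation")
  # each direction episode has exactly 2*round(5*fs) samples
  expect_equal(seg$end_sample - seg$start_sample, rep(2 * round(5 * fs), 2))
  # zero trials -> all-rest trace
  cue0 <- generate_cue(cue_profile(1, 1, n_trials = 0, rest_duration = 2,
                                   sample_rate = fs))
  expect_equal(ncol(cue0$angles), round(2 * fs))
  expect_true(all(cue0$angles == 0))
  expect_error(cue_profile(1, ramp_duration = 0), class = "mukin_error")
})

test_that("recruitment ladder spans exactly the recruitment range", {
  p <- build_pool(30, recruitment_range = 30, seed = 1)
  thr <- p$recruitment_thresholds
  expect_true(all(diff(thr) > 0))
  expect_equal(thr[30] / thr[1], 30, tolerance = 1e-9)
  expect_equal(thr[30], 1.0)
  expect_equal(build_pool(1, 30)$recruitment_thresholds, 1.0)
  expect_error(build_pool(0, 30), class = "mukin_error")
  expect_error(build_pool(10, 0.5), class = "mukin_error")
  expect_true(all(diff(p$amplitude_scales) > 0))
})

test_that("common drive is the rectified normalized angle", {
  kin <- kinematics_trace(rbind(c(0, 60, -30, 90), 0, 0), 2048)
  expect_equal(drive_from_kinematics(kin, 1, +1, 60), c(0, 1, 0, 1))
  expect_equal(drive_from_kinematics(kin, 1, -1, 60), c(0, 0, 0.5, 0))
  expect_error(drive_from_kinematics(kin, 4, 1, 60), class = "mukin_error")
  expect_error(drive_from_kinematics(kin, 1, 1, -1), class = "mukin_error")
})

test_that("spike trains respect thresholds, rates and recruitment order", {
  fs <- 2048
  pool <- build_pool(5, recruitment_range = 10, min_rate = 8, peak_rate = 35,
                     rate_gain = 30, isi_cov = 0, seed = 3)
  # subthreshold drive -> silence
  sp0 <- sample_spike_trains(pool, rep(0, fs), fs, seed = 1)
  expect_true(all(lengths(sp0$units) == 0))

  # constant maximal drive, deterministic intervals: count matches the rate
  sp1 <- sample_spike_trains(pool, rep(1, 10 * fs), fs, seed = 1)
  for (j in 1:5) {
    rate <- min(35, 8 + 30 * (1 - pool$recruitment_thresholds[j]))
    expect_lte(abs(length(sp1$units[[j]]) - 10 * rate), 1)
    expect_false(is.unsorted(sp1$units[[j]], strictly = TRUE))
  }

  # empirical ISI CoV recovers the configured value
  pool_cv <- build_pool(1, recruitment_range = 30, min_rate = 8,
                        peak_rate = 35, isi_cov = 0.15, seed = 4)
  pool_cv$recruitment_thresholds <- 0.5
  sp2 <- sample_spike_trains(pool_cv, rep(1, 100 * fs), fs, seed = 9)
  isi <- diff(sp2$units[[1]])
  expect_lt(abs(sd(isi) / mean(isi) - 0.15), 0.03)

  # recruitment order under monotone drive, no ISI noise
  pool0 <- build_pool(8, recruitment_range = 20, isi_cov = 0, seed = 5)
  drive <- seq(0, 1, length.out = 4 * fs)
  sp3 <- sample_spike_trains(pool0, drive, fs, seed = 2)
  first <- vapply(sp3$units, function(u) u[1], 0)
  expect_false(is.unsorted(first))

  # determinism
  sp4 <- sample_spike_trains(pool0, drive, fs, seed = 2)
  expect_identical(sp3$units, sp4$units)
  expect_error(sample_spike_trains(pool0, drive, fs = -1),
               class = "mukin_error")
})

test_that("MUAP templates decay from the territory centre and scale with size", {
  pool <- build_pool(2, recruitment_range = 5, grid_shape = c(8, 8),
                     center = c(4, 4), center_spread = 0, seed = 7)
  pool$amplitude_scales <- c(1, 2)
  bank <- generate_templates(pool, c(8, 8), template_length = 51, seed = 7)
  for (j in 1:2) {
    tmpl <- bank_template(bank, pool$unit_ids[j])
    peaks <- apply(abs(tmpl), 1, max)
    ctr <- (4 - 1) * 8 + 4 # channel (4,4), row-major
    expect_equal(which.max(peaks), ctr)
  }
  t1 <- bank_template(bank, pool$unit_ids[1])
  t2 <- bank_template(bank, pool$unit_ids[2])
  expect_equal(max(abs(t2)) / max(abs(t1)), 2, tolerance = 1e-9)
  expect_error(generate_templates(pool, c(8, 8), template_length = 2),
               class = "mukin_error")
})

test_that("EMG synthesis is an exact superposition and is seed-deterministic", {
  pool <- build_pool(1, 5, seed = 11, grid_shape = c(2, 2))
  bank <- generate_templates(pool, c(2, 2), 21, seed = 11)
  tmpl <- bank_template(bank, "u001")
  off <- bank$offsets[["u001"]]

  sp <- spike_train_set(list(u001 = 100L))
  emg <- synthesize_emg(sp, bank, fs = 2048, n_samples = 400,
                        grid_shape = c(2, 2), noise_snr_db = Inf)
  expect_equal(emg$samples[, (100 - off + 1):(100 - off + 21)], tmpl)
  expect_true(all(emg$samples[, 1:(100 - off)] == 0))

  # two overlapping discharges sum sample-wise
  sp2 <- spike_train_set(list(u001 = c(100L, 110L)))
  emg2 <- synthesize_emg(sp2, bank, 2048, 400, c(2, 2), Inf)
  brute <- matrix(0, 4, 400)
  for (t0 in c(100, 110))
    brute[, (t0 - off + 1):(t0 - off + 21)] <-
      brute[, (t0 - off + 1):(t0 - off + 21)] + tmpl
  expect_equal(emg2$samples, brute)

  # mixture linearity with noise disabled
  pool2 <- build_pool(2, 5, seed = 12, grid_shape = c(2, 2))
  bank2 <- generate_templates(pool2, c(2, 2), 21, seed = 12)
  spA <- spike_train_set(list(u001 = c(50L, 90L)))
  spB <- spike_train_set(list(u002 = c(60L, 200L)))
  spAB <- spike_train_set(list(u001 = c(50L, 90L), u002 = c(60L, 200L)))
  eA <- synthesize_emg(spA, bank2, 2048, 300, c(2, 2), Inf)$samples
  eB <- synthesize_emg(spB, bank2, 2048, 300, c(2, 2), Inf)$samples
  eAB <- synthesize_emg(spAB, bank2, 2048, 300, c(2, 2), Inf)$samples
  expect_equal(eAB, eA + eB)

  # deterministic under a fixed seed, including noise
  n1 <- synthesize_emg(sp, bank, 2048, 400, c(2, 2), 10, seed = 5)$samples
  n2 <- synthesize_emg(sp, bank, 2048, 400, c(2, 2), 10, seed = 5)$samples
  expect_identical(n1, n2)
  expect_error(synthesize_emg(spike_train_set(list(u001 = 500L)), bank,
                              2048, 400, c(2, 2), Inf),
               class = "mukin_error")
})

test_that("achieved synthesis SNR matches the requested level", {
  pool <- build_pool(5, 10, seed = 21, grid_shape = c(4, 4))
  bank <- generate_templates(pool, c(4, 4), 31, seed = 21)
  fs <- 2048
  sp <- sample_spike_trains(pool, rep(1, 4 * fs), fs, seed = 3)
  clean <- synthesize_emg(sp, bank, fs, 4 * fs, c(4, 4), Inf)$samples
  noisy <- synthesize_emg(sp, bank, fs, 4 * fs, c(4, 4), 12, seed = 3)$samples
  noise <- noisy - clean
  act <- colSums(abs(clean)) > 0
  p_ch <- rowMeans(clean[, act]^2)
  snr <- mean(10 * log10(p_ch[p_ch > 0] / rowMeans(noise^2)[p_ch > 0]))
  expect_lt(abs(snr - 12), 0.5)
})

test_that("corruption retains, deletes and inserts as specified", {
  pool <- build_pool(10, 10, seed = 31)
  sp <- spike_train_set(setNames(
    lapply(1:10, function(j) sort(sample.int(20000, 500)) - 1L),
    pool$unit_ids))

  ident <- corrupt_spike_trains(sp, corruption_spec(0, 0, 1, 1), pool,
                                20000, 2048, seed = 1)
  expect_identical(ident$units, sp$units)
  expect_identical(ident$provenance, "corrupted")

  gone <- corrupt_spike_trains(sp, corruption_spec(1, 0, 1, 1), pool,
                               20000, 2048, seed = 1)
  expect_true(all(lengths(gone$units) == 0))

  part <- corrupt_spike_trains(sp, corruption_spec(0, 0, 0.6, 1), pool,
                               20000, 2048, seed = 2)
  expect_equal(length(part$units), ceiling(0.6 * 10))

  # 20% deletions: binomial mean over 50 seeds within ~2 sigma
  one <- spike_train_set(list(u = sort(sample.int(1e6, 1000)) - 1L))
  pool1 <- list(unit_ids = "u", recruitment_thresholds = 0.5)
  kept <- vapply(1:50, function(s)
    length(corrupt_spike_trains(one, corruption_spec(0.2, 0, 1, 1), pool1,
                                1e6, 2048, seed = s)$units[[1]]), 0)
  expect_lt(abs(mean(kept) - 800), 25)
  expect_error(corruption_spec(miss_rate = 1.5), class = "mukin_error")
})

test_that("sessions are bit-identical under one seed and differ across seeds", {
  s1 <- small_session(seed = 5)
  s2 <- small_session(seed = 5)
  expect_identical(s1$emg$samples, s2$emg$samples)
  expect_identical(s1$spikes$units, s2$spikes$units)
  expect_identical(s1$kin$angles, s2$kin$angles)
  s3 <- small_session(seed = 6)
  expect_false(identical(s1$emg$samples, s3$emg$samples))
  # a few multi-DoF units exist at the default sharing fraction
  expect_identical(dim(s1$kin$angles), c(3L, ncol(s1$emg$samples)))
})
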