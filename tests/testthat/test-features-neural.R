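test_that("windowed spike counts enumerate and conserve discharges", {
  spec <- window_spec()
  sp <- spike_train_set(list(a = c(0L, 100L, 204L), b = integer(0)))
  m <- spike_counts(sp, spec, 2048, 2048)
  expect_equal(unname(m[1, "a"]), 3L)
  expect_true(all(m[, "b"] == 0L))

  # conservation over a disjoint tiling (step = window length)
  set.seed(5)
  train <- sort(sample.int(20000, 400)) - 1L
  tile <- window_spec(window_length = 0.1, step = 0.1)
  mt <- spike_counts(spike_train_set(list(u = train)), tile, 20000, 2048)
  n_cov <- max(segment_windows(20000, tile, 2048)$end)
  expect_equal(sum(mt[, "u"]), sum(train < n_cov))

  # against the brute-force oracle
  w <- segment_windows(20000, spec, 2048)
  ms <- spike_counts(spike_train_set(list(u = train)), spec, 20000, 2048)
  for (k in sample(nrow(w), 25))
    expect_equal(unname(ms[k, "u"]),
                 oracle_spike_count(train, w$start[k], w$end[k]))
})

test_that("spike-triggered averaging recovers generating templates", {
  pool <- build_pool(1, 5, seed = 41, grid_shape = c(2, 2))
  bank <- generate_templates(pool, c(2, 2), 31, seed = 41)
  tmpl <- bank_template(bank, "u001")
  off <- bank$offsets[["u001"]]
  sp <- seq(100L, 9800L, by = 60L) # sparse, non-overlapping
  emg <- synthesize_emg(spike_train_set(list(u001 = sp)), bank, 2048, 10000,
                        c(2, 2), Inf)
  sta <- spike_triggered_average(emg, sp, 31, off)
  expect_equal(unclass(sta)[, ], tmpl[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(sta, "n_spikes"), length(sp))

  # averaging law: with additive noise the STA error SD shrinks as 1/sqrt(n)
  set.seed(6)
  noise_sd <- 0.5
  noisy <- emg
  noisy$samples <- noisy$samples + matrix(rnorm(length(noisy$samples), 0,
                                                noise_sd), 4)
  sta_n <- spike_triggered_average(noisy, sp, 31, off)
  err_sd <- sd(sta_n - tmpl)
  expect_lt(abs(err_sd - noise_sd / sqrt(length(sp))),
            3 * noise_sd / sqrt(length(sp)))

  expect_error(spike_triggered_average(emg, c(100L, 200L, 300L), 31, off,
                                       min_spikes = 10),
               class = "mukin_error")
})

test_that("unit matching applies the correlation and channel rules", {
  pool <- build_pool(3, 5, seed = 51, grid_shape = c(3, 3), center = c(2, 2),
                     center_spread = 0.8)
  bank <- generate_templates(pool, c(3, 3), 41, seed = 51)
  noise_sd <- rep(1e-3, 9)

  self <- match_units(bank, bank, noise_sd)
  diag_pairs <- self$pairs[self$pairs$unit_a == self$pairs$unit_b, ]
  expect_equal(diag_pairs$correlation, rep(1, 3), tolerance = 1e-12)
  expect_true(all(diag_pairs$matched))

  # negated templates anti-correlate and are not matched
  neg <- bank; neg$gains <- -neg$gains
  m_neg <- match_units(bank, neg, noise_sd)
  d <- m_neg$pairs[m_neg$pairs$unit_a == m_neg$pairs$unit_b, ]
  expect_equal(d$correlation, rep(-1, 3), tolerance = 1e-12)
  expect_false(any(d$matched))

  # a 5-sample shift of a zero-padded template is recovered at max lag
  w <- numeric(41); w[16:26] <- sin(seq(0, pi, length.out = 11))
  bA <- muap_bank("x", 41, 20L, waveforms = cbind(w), gains = cbind(1))
  bB <- muap_bank("x", 41, 20L, waveforms = cbind(c(numeric(5), w[1:36])),
                  gains = cbind(1))
  ms <- match_units(bA, bB, 0)
  expect_equal(ms$pairs$correlation, 1, tolerance = 1e-9)
  expect_true(ms$pairs$matched)

  # symmetry of the lag-maximized correlation
  mab <- match_units(bank, neg, noise_sd)$pairs
  mba <- match_units(neg, bank, noise_sd)$pairs
  key <- function(p) paste(pmin(p$unit_a, p$unit_b), pmax(p$unit_a, p$unit_b))
  expect_equal(mab$correlation[order(key(mab))],
               mba$correlation[order(key(mba))], tolerance = 1e-12)

  # the 25%-above-noise channel rule against a hand enumeration
  set.seed(8)
  for (i in 1:20) {
    b1 <- generate_templates(build_pool(1, 5, seed = 100 + i,
                                        grid_shape = c(3, 3)),
                             c(3, 3), 21, seed = 100 + i)
    nsd <- runif(9, 0, max(abs(bank_template(b1, "u001"))))
    res <- match_units(b1, b1, nsd)
    peaks <- apply(abs(bank_template(b1, "u001")), 1, max)
    expected <- sum(peaks > 1.25 * nsd)
    if (expected == 0) {
      expect_false(res$pairs$matched)
      expect_equal(res$pairs$reason, "no_admissible_channels")
    } else {
      expect_equal(res$pairs$n_channels, expected)
    }
  }
})

test_that("reconstruction explains noiseless EMG and misses corrupted spikes", {
  pool <- build_pool(4, 8, seed = 61, grid_shape = c(2, 4))
  bank <- generate_templates(pool, c(2, 4), 31, seed = 61)
  fs <- 2048
  drive <- rep(0.9, 6 * fs)
  sp <- sample_spike_trains(pool, drive, fs, seed = 13)
  emg <- synthesize_emg(sp, bank, fs, length(drive), c(2, 4), Inf)

  recon <- reconstruct_emg(sp, bank, length(drive), fs, c(2, 4))
  res <- residual_emg(emg, recon)
  expect_lt(sum(res$samples^2) / sum(emg$samples^2), 1e-12)

  # dropping 20% of spikes strictly increases the residual energy
  set.seed(14)
  sp_miss <- spike_train_set(lapply(sp$units, function(u)
    u[runif(length(u)) >= 0.2]), "corrupted")
  res_miss <- residual_emg(emg, reconstruct_emg(sp_miss, bank,
                                                length(drive), fs, c(2, 4)))
  expect_gt(sum(res_miss$samples^2), sum(res$samples^2))

  # zero spikes -> zero reconstruction
  empty <- spike_train_set(list(u001 = integer(0)))
  expect_true(all(reconstruct_emg(empty, bank, 100, fs)$samples == 0))

  bad <- emg_recording(matrix(0, 2, 10), fs, c(1, 2))
  expect_error(residual_emg(emg, bad), class = "mukin_error")
  expect_error(reconstruct_emg(spike_train_set(list(zz = 5L)), bank, 100,
                               fs, require_all = TRUE),
               class = "mukin_error")
})

test_that("comparison feature sets assemble with the documented PCA layout", {
  set.seed(15)
  dsc <- matrix(rpois(200 * 12, 3), 200)
  colnames(dsc) <- sprintf("u%02d", 1:12)
  res_td <- matrix(rnorm(200 * 8), 200)

  raw <- assemble_feature_set("DSC", dsc)
  expect_identical(raw, dsc)

  am2 <- assemble_feature_set("AM2", dsc)
  b2 <- attr(am2, "basis")
  expect_equal(ncol(am2), b2$retained)
  expect_gte(sum(b2$explained[seq_len(b2$retained)]), 0.98 - 1e-9)

  am1 <- assemble_feature_set("AM1", dsc, res_td)
  expect_gte(ncol(am1), 1)
  # training basis applied unchanged to new data
  am1b <- assemble_feature_set("AM1", dsc[1:50, ], res_td[1:50, ],
                               basis = attr(am1, "basis"))
  expect_equal(am1b[1:50, ], am1[1:50, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(assemble_feature_set("AM1", dsc, res_td[1:100, ]),
               class = "mukin_error")
})
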