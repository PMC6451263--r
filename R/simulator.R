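# Synthetic session generator: triangular kinematic cues, recruitment-ordered
# motor neuron pools driven by a kinematics-derived common drive, multichannel
# MUAP templates mixed into EMG, and decomposition-error corruption.

#' Cue profile for single-DoF triangular ramps
#'
#' Each trial is neutral -> +rom -> neutral, rest, neutral -> -rom -> neutral,
#' with rests between trials; the trace starts and ends at 0 degrees and the
#' slope magnitude is constant within a ramp.
#'
#' @param dof_index cued DoF, 1..3.
#' @param ramp_duration duration of one ramp leg in seconds (the study speeds
#'   are 5, 2.5 and 1 s).
#' @param n_trials trials per DoF (default 3).
#' @param rom half range of motion per direction in degrees.
#' @param rest_duration rest between ramps in seconds.
#' @param sample_rate Hz.
#' @export
cue_profile <- function(dof_index, ramp_duration, n_trials = 3L, rom = 60,
                        rest_duration = 2, sample_rate = 2048) {
  if (ramp_duration <= 0 || sample_rate <= 0)
    stop_mukin("invalid_configuration",
               "ramp_duration and sample_rate must be positive")
  if (!dof_index %in% 1:3)
    stop_mukin("invalid_argument", "dof_index must be 1, 2 or 3")
  if (n_trials < 0) stop_mukin("invalid_configuration", "n_trials must be >= 0")
  if (rom <= 0) stop_mukin("invalid_configuration", "rom must be positive")
  structure(list(dof_index = as.integer(dof_index),
                 ramp_duration = ramp_duration, n_trials = as.integer(n_trials),
                 rom = rom, rest_duration = rest_duration,
                 sample_rate = sample_rate), class = "cue_profile")
}

triangular_episode <- function(nramp, rom, direction) {
  # 2*nramp samples of nonzero slope: rise 1..nramp, fall nramp-1..0
  direction * rom * c(seq_len(nramp), rev(seq_len(nramp)) - 1L) / nramp
}

#' Generate the kinematic cue for one DoF
#'
#' @param profile a [cue_profile()].
#' @return a [kinematics_trace()] (3 x T; the uncued DoFs are identically 0)
#'   with attribute `"segmentation"`, a [trial_segmentation()] of the ramp
#'   episodes.
#' @export
generate_cue <- function(profile) {
  stopifnot(inherits(profile, "cue_profile"))
  fs <- profile$sample_rate
  nramp <- as.integer(round(profile$ramp_duration * fs))
  nrest <- as.integer(round(profile$rest_duration * fs))
  pieces <- list()
  seg <- list()
  pos <- 0L
  for (k in seq_len(profile$n_trials)) {
    for (dir in c(1, -1)) {
      pieces[[length(pieces) + 1L]] <- numeric(nrest)
      pos <- pos + nrest
      ep <- triangular_episode(nramp, profile$rom, dir)
      seg[[length(seg) + 1L]] <- data.frame(
        trial_id = sprintf("d%dt%d", profile$dof_index, k),
        dof = profile$dof_index, direction = dir,
        start_sample = pos, end_sample = pos + length(ep),
        ramp_duration_s = profile$ramp_duration)
      pieces[[length(pieces) + 1L]] <- ep
      pos <- pos + length(ep)
    }
  }
  pieces[[length(pieces) + 1L]] <- numeric(nrest)
  cue <- unlist(pieces) %||% numeric(nrest)
  angles <- matrix(0, 3L, length(cue))
  angles[profile$dof_index, ] <- cue
  out <- kinematics_trace(angles, fs)
  attr(out, "segmentation") <- trial_segmentation(
    if (length(seg)) do.call(rbind, seg) else
      data.frame(trial_id = character(0), dof = integer(0),
                 direction = numeric(0), start_sample = integer(0),
                 end_sample = integer(0), ramp_duration_s = numeric(0)))
  out
}

#' Build a recruitment-ordered motor neuron pool
#'
#' Recruitment thresholds follow a geometric ladder whose largest/smallest
#' ratio equals `recruitment_range`, spanning `1/recruitment_range` to 1 of
#' the maximal drive. MUAP amplitude scales increase with threshold (larger,
#' later-recruited units have larger action potentials).
#'
#' @param n_units units in the pool.
#' @param recruitment_range ratio of largest to smallest threshold (> 1).
#' @param min_rate,peak_rate discharge rates at recruitment and saturation
#'   (discharges/s).
#' @param rate_gain rate increase per unit of excess drive (discharges/s).
#' @param isi_cov coefficient of variation of inter-spike intervals.
#' @param grid_shape electrode grid `(rows, cols)` for territory placement.
#' @param center optional pool territory locus `(row, col)`; random if NULL.
#' @param center_spread SD (in inter-electrode distances) of unit territory
#'   centers around the locus.
#' @param seed integer seed.
#' @export
build_pool <- function(n_units, recruitment_range = 30, min_rate = 8,
                       peak_rate = 35, rate_gain = 30, isi_cov = 0.15,
                       grid_shape = c(8L, 8L), center = NULL,
                       center_spread = 1.0, seed = 1L) {
  if (n_units < 1) stop_mukin("invalid_configuration", "n_units must be >= 1")
  if (recruitment_range <= 1)
    stop_mukin("invalid_configuration", "recruitment_range must be > 1")
  if (min_rate >= peak_rate)
    stop_mukin("invalid_configuration", "min_rate must be below peak_rate")
  if (isi_cov < 0) stop_mukin("invalid_configuration", "isi_cov must be >= 0")
  thresholds <- if (n_units == 1L) 1.0 else
    recruitment_range^((seq_len(n_units) - 1) / (n_units - 1)) /
      recruitment_range
  set.seed(derive_seed(seed, "pool"))
  if (is.null(center))
    center <- c(stats::runif(1, 1, grid_shape[1]),
                stats::runif(1, 1, grid_shape[2]))
  centers <- cbind(
    pmin(pmax(stats::rnorm(n_units, center[1], center_spread), 1),
         grid_shape[1]),
    pmin(pmax(stats::rnorm(n_units, center[2], center_spread), 1),
         grid_shape[2]))
  structure(list(n_units = as.integer(n_units),
                 unit_ids = sprintf("u%03d", seq_len(n_units)),
                 recruitment_thresholds = thresholds,
                 min_rate = min_rate, peak_rate = peak_rate,
                 rate_gain = rate_gain, isi_cov = isi_cov,
                 territory_centers = centers,
                 amplitude_scales = 0.5 + 0.5 * sqrt(thresholds),
                 grid_shape = as.integer(grid_shape)),
            class = "motor_unit_pool")
}

#' Common drive from joint angle
#'
#' The drive to a direction pool is the rectified normalized angle,
#' `clip(direction * angle / rom, 0, 1)`.
#'
#' @param kin a [kinematics_trace()].
#' @param dof DoF index 1..3.
#' @param direction +1 or -1.
#' @param rom half range of motion, degrees (> 0).
#' @return numeric drive trace in `[0, 1]`.
#' @export
drive_from_kinematics <- function(kin, dof, direction, rom) {
  if (rom <= 0) stop_mukin("invalid_configuration", "rom must be positive")
  if (!dof %in% 1:3) stop_mukin("invalid_argument", "dof out of range")
  if (!direction %in% c(-1, 1))
    stop_mukin("invalid_argument", "direction must be +1 or -1")
  clip01(direction * kin$angles[dof, ] / rom)
}

firing_rate <- function(drive, thr, min_rate, peak_rate, rate_gain) {
  pmin(min_rate + rate_gain * (drive - thr), peak_rate)
}

#' Sample motor unit spike trains from a drive trace
#'
#' A unit is silent while the drive is below its recruitment threshold;
#' above it, the instantaneous rate is
#' `min(peak_rate, min_rate + rate_gain * (drive - threshold))`. Inter-spike
#' intervals are Gaussian with the model mean and CoV `isi_cov`, rejecting
#' intervals at or below the 1 ms refractory period. The first discharge of a
#' recruitment episode occurs at the threshold crossing.
#'
#' @param pool a [build_pool()] result.
#' @param drive numeric trace in `[0, 1]`.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param refractory refractory period, seconds.
#' @return a [spike_train_set()] with 0-based, strictly increasing indices.
#' @export
sample_spike_trains <- function(pool, drive, fs, seed = 1L,
                                refractory = 0.001) {
  if (fs <= 0) stop_mukin("invalid_configuration", "fs must be positive")
  if (any(drive < 0 | drive > 1))
    stop_mukin("invalid_input", "drive must lie in [0, 1]")
  set.seed(derive_seed(seed, "spikes"))
  n <- length(drive)
  units <- vector("list", pool$n_units)
  for (j in seq_len(pool$n_units)) {
    thr <- pool$recruitment_thresholds[j]
    act <- drive >= thr
    if (!any(act)) { units[[j]] <- integer(0); next }
    r <- rle(act)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts, ends)[r$values, , drop = FALSE]
    sp <- numeric(0)
    for (k in seq_len(nrow(runs))) {
      t <- as.numeric(runs[k, 1L]); e <- runs[k, 2L]
      repeat {
        sp <- c(sp, t)
        rate <- firing_rate(drive[max(1L, floor(t))], thr, pool$min_rate,
                            pool$peak_rate, pool$rate_gain)
        mu <- fs / rate
        if (pool$isi_cov > 0) {
          repeat {
            isi <- mu * (1 + pool$isi_cov * stats::rnorm(1))
            if (isi > refractory * fs) break
          }
        } else isi <- mu
        t <- t + isi
        if (t > e) break
      }
    }
    units[[j]] <- sort(unique(as.integer(round(sp)) - 1L))
  }
  spike_train_set(stats::setNames(units, pool$unit_ids), "ground_truth")
}

#' Generate multichannel MUAP templates for a pool
#'
#' Each unit's waveform is a randomized biphasic/triphasic shape (mixture of
#' first and second Gaussian derivatives), cropped so the peak-energy sample
#' sits at the template centre; channel amplitudes decay as a Gaussian of grid
#' distance from the unit's territory centre and the maximal-channel peak
#' equals the unit's `amplitude_scale` exactly.
#'
#' @param pool a [build_pool()] result.
#' @param grid_shape electrode grid `(rows, cols)`.
#' @param template_length template support in samples (>= 3, odd recommended).
#' @param seed integer seed.
#' @param spatial_decay Gaussian decay SD in inter-electrode distances.
#' @return an object of class `muap_bank` (separable representation).
#' @export
generate_templates <- function(pool, grid_shape = pool$grid_shape,
                               template_length = 51L, seed = 1L,
                               spatial_decay = 1.5) {
  if (is.null(pool) || pool$n_units < 1)
    stop_mukin("invalid_argument", "pool must contain at least one unit")
  if (template_length < 3)
    stop_mukin("invalid_argument", "template_length must be >= 3 samples")
  set.seed(derive_seed(seed, "templates"))
  L <- as.integer(template_length)
  C <- prod(grid_shape)
  ch_row <- ((seq_len(C) - 1L) %/% grid_shape[2]) + 1L
  ch_col <- ((seq_len(C) - 1L) %% grid_shape[2]) + 1L
  waveforms <- matrix(0, L, pool$n_units)
  gains <- matrix(0, C, pool$n_units)
  M <- 4L * L + 1L
  tt <- seq_len(M) - (M + 1L) / 2
  for (j in seq_len(pool$n_units)) {
    sigma <- stats::runif(1, max(2, L / 16), max(3, L / 7))
    phi <- stats::runif(1, -0.6, 0.6)
    g <- exp(-tt^2 / (2 * sigma^2))
    g1 <- -tt / sigma^2 * g
    g2 <- (tt^2 / sigma^4 - 1 / sigma^2) * g
    w <- cos(phi) * g1 / max(abs(g1)) + sin(phi) * g2 / max(abs(g2))
    p <- which.max(w^2)
    h <- (L - 1L) %/% 2L
    idx <- (p - h):(p - h + L - 1L)
    w <- w[pmin(pmax(idx, 1L), M)] * (idx >= 1L & idx <= M)
    waveforms[, j] <- w / max(abs(w))
    d2 <- (ch_row - pool$territory_centers[j, 1])^2 +
      (ch_col - pool$territory_centers[j, 2])^2
    decay <- exp(-d2 / (2 * spatial_decay^2))
    gains[, j] <- pool$amplitude_scales[j] * decay / max(decay)
  }
  offsets <- apply(waveforms^2, 2L, which.max) - 1L
  muap_bank(unit_ids = pool$unit_ids, template_length = L, offsets = offsets,
            waveforms = waveforms, gains = gains)
}

#' MUAP template bank
#'
#' Holds per-unit multichannel action potential waveforms, either in separable
#' form (`waveforms` L x U and `gains` C x U, template = gain outer waveform)
#' or as a list of full channels x L matrices (e.g. spike-triggered averages).
#' `offsets` give, per unit, the 0-based sample of the template that a
#' discharge index marks (the peak-energy sample by convention).
#'
#' @param unit_ids character vector of unit identifiers.
#' @param template_length template support, samples.
#' @param offsets integer vector of 0-based alignment offsets.
#' @param waveforms,gains separable representation (optional).
#' @param templates list of channels x L matrices (optional).
#' @export
muap_bank <- function(unit_ids, template_length, offsets, waveforms = NULL,
                      gains = NULL, templates = NULL) {
  if (is.null(templates) && (is.null(waveforms) || is.null(gains)))
    stop_mukin("invalid_argument",
               "provide either templates or waveforms + gains")
  lens <- if (!is.null(templates))
    vapply(templates[!vapply(templates, is.null, TRUE)], ncol, 1L) else
      nrow(waveforms)
  if (length(lens) && any(lens != template_length))
    stop_mukin("invalid_input", "all templates must share template_length")
  structure(list(unit_ids = unit_ids,
                 template_length = as.integer(template_length),
                 offsets = stats::setNames(as.integer(offsets), unit_ids),
                 waveforms = waveforms, gains = gains, templates = templates),
            class = "muap_bank")
}

#' Extract one unit's full channels x L template from a bank
#' @param bank a [muap_bank()]. @param unit_id unit identifier.
#' @return channels x L numeric matrix, or NULL if absent.
#' @export
bank_template <- function(bank, unit_id) {
  if (!is.null(bank$templates)) return(bank$templates[[unit_id]])
  j <- match(unit_id, bank$unit_ids)
  if (is.na(j)) return(NULL)
  outer(bank$gains[, j], bank$waveforms[, j])
}

#' Synthesize multichannel EMG from spike trains and a template bank
#'
#' Each channel is the superposition of every unit's template placed at its
#' discharge indices (the discharge marks the template's alignment sample;
#' placements that do not fit fully inside the trace are skipped), plus white
#' Gaussian noise scaled so the channel-mean SNR during activity equals
#' `noise_snr_db`. With an empty mixture, noise with absolute SD `noise_sd`
#' is returned instead.
#'
#' @param spikes a [spike_train_set()].
#' @param bank a [muap_bank()].
#' @param fs sampling rate, Hz.
#' @param n_samples trace length.
#' @param grid_shape electrode grid `(rows, cols)`.
#' @param noise_snr_db channel-mean SNR in dB (`Inf` for noiseless).
#' @param noise_sd absolute noise SD used when the mixture is empty.
#' @param seed integer seed (noise is deterministic given the seed).
#' @export
synthesize_emg <- function(spikes, bank, fs, n_samples, grid_shape,
                           noise_snr_db = 15, noise_sd = 1, seed = 1L) {
  n <- as.integer(n_samples)
  C <- prod(grid_shape)
  all_sp <- unlist(spikes$units, use.names = FALSE)
  if (length(all_sp) && (max(all_sp) >= n || min(all_sp) < 0))
    stop_mukin("out_of_bounds", "spike index beyond trace length")
  clean <- matrix(0, C, n)
  sep <- !is.null(bank$waveforms)
  for (id in names(spikes$units)) {
    sp <- spikes$units[[id]]
    if (!length(sp)) next
    j <- match(id, bank$unit_ids)
    if (is.na(j)) next
    starts0 <- sp - bank$offsets[[id]]
    if (sep) {
      conv <- overlay_waveform(starts0, bank$waveforms[, j], n)
      nz <- which(conv != 0)
      if (length(nz))
        clean[, nz] <- clean[, nz] + bank$gains[, j] %o% conv[nz]
    } else {
      ov <- overlay_template_matrix(starts0, bank$templates[[id]], n)
      if (length(ov$cols))
        clean[, ov$cols] <- clean[, ov$cols] + ov$block
    }
  }
  if (is.finite(noise_snr_db)) {
    set.seed(derive_seed(seed, "noise"))
    act <- colSums(abs(clean)) > 0
    if (any(act)) {
      p_ch <- rowMeans(clean[, act, drop = FALSE]^2)
      p_ch <- p_ch[p_ch > 0]
      sigma2 <- 10^((mean(10 * log10(p_ch)) - noise_snr_db) / 10)
      sd_n <- sqrt(sigma2)
    } else sd_n <- noise_sd
    clean <- clean + matrix(stats::rnorm(C * n, 0, sd_n), C, n)
  }
  emg_recording(clean, fs, grid_shape)
}

#' Decomposition-error corruption specification
#'
#' @param miss_rate probability of deleting each true discharge.
#' @param false_positive_rate spurious discharges per second per unit.
#' @param detected_fraction fraction of units retained (sampled with weight
#'   `threshold^high_threshold_bias`, emulating the bias of surface EMG
#'   decomposition towards large high-threshold units).
#' @param high_threshold_bias nonnegative weight exponent.
#' @export
corruption_spec <- function(miss_rate = 0, false_positive_rate = 0,
                            detected_fraction = 1, high_threshold_bias = 1) {
  if (miss_rate < 0 || miss_rate > 1)
    stop_mukin("invalid_configuration", "miss_rate must be in [0, 1]")
  if (false_positive_rate < 0)
    stop_mukin("invalid_configuration", "false_positive_rate must be >= 0")
  if (detected_fraction <= 0 || detected_fraction > 1)
    stop_mukin("invalid_configuration", "detected_fraction must be in (0, 1]")
  if (high_threshold_bias < 0)
    stop_mukin("invalid_configuration", "high_threshold_bias must be >= 0")
  structure(list(miss_rate = miss_rate,
                 false_positive_rate = false_positive_rate,
                 detected_fraction = detected_fraction,
                 high_threshold_bias = high_threshold_bias),
            class = "corruption_spec")
}

#' Apply decomposition-error corruption to spike trains
#'
#' Retains `ceil(detected_fraction * n_units)` units sampled with probability
#' weight `threshold^high_threshold_bias`, deletes each retained discharge
#' independently with probability `miss_rate`, and inserts spurious discharges
#' as a homogeneous process at `false_positive_rate` per second. Output trains
#' are sorted and deduplicated.
#'
#' @param spikes a [spike_train_set()].
#' @param spec a [corruption_spec()].
#' @param pool pool (or combined pool) carrying `recruitment_thresholds` and
#'   `unit_ids` matching `spikes`.
#' @param n_samples,fs recording length and rate (for the false-positive
#'   process).
#' @param seed integer seed.
#' @export
corrupt_spike_trains <- function(spikes, spec, pool, n_samples, fs,
                                 seed = 1L) {
  stopifnot(inherits(spec, "corruption_spec"))
  set.seed(derive_seed(seed, "corrupt"))
  ids <- names(spikes$units)
  thr <- pool$recruitment_thresholds[match(ids, pool$unit_ids)]
  n_keep <- ceiling(spec$detected_fraction * length(ids))
  keep_ids <- if (n_keep >= length(ids)) ids else
    sample(ids, n_keep, prob = thr^spec$high_threshold_bias)
  keep_ids <- ids[ids %in% keep_ids]  # preserve original ordering
  dur_s <- n_samples / fs
  out <- lapply(keep_ids, function(id) {
    sp <- spikes$units[[id]]
    if (spec$miss_rate > 0 && length(sp))
      sp <- sp[stats::runif(length(sp)) >= spec$miss_rate]
    if (spec$false_positive_rate > 0) {
      n_fp <- stats::rpois(1, spec$false_positive_rate * dur_s)
      if (n_fp > 0)
        sp <- c(sp, sample.int(n_samples, n_fp, replace = TRUE) - 1L)
    }
    sort(unique(as.integer(sp)))
  })
  spike_train_set(stats::setNames(out, keep_ids), "corrupted")
}

pool_loci <- function(grid_shape) {
  r <- grid_shape[1]; c <- grid_shape[2]
  rows <- 1 + c(0.25, 0.75) * (r - 1)
  cols <- 1 + c(0.17, 0.5, 0.83) * (c - 1)
  as.matrix(expand.grid(row = rows, col = cols))[1:6, , drop = FALSE]
}

#' Simulate a complete single-speed recording session
#'
#' Generates one session at one ramp speed: triangular single-DoF cues (three
#' DoFs, `n_trials` trials each, session order seeded-random), six
#' direction-specific agonist pools (one per DoF direction, territory loci
#' spread over the grid) with a configurable fraction of units shared across
#' DoFs, spike trains from the kinematics-driven common drive, multichannel
#' EMG at the requested SNR, and optionally a corrupted copy of the spike
#' trains emulating imperfect decomposition.
#'
#' @param ramp_duration ramp leg duration, seconds (5, 2.5 or 1 in the study
#'   protocol).
#' @param n_trials trials per DoF.
#' @param units_per_pool motor units per direction pool.
#' @param grid_shape electrode grid `(rows, cols)`.
#' @param snr_db channel-mean EMG SNR in dB (`Inf` = noiseless).
#' @param corruption optional [corruption_spec()]; when given,
#'   `$spikes_dec` holds the corrupted trains, else the ground truth.
#' @param rom,rest_duration,sample_rate cue parameters.
#' @param recruitment_range,min_rate,peak_rate,rate_gain,isi_cov pool
#'   parameters (see [build_pool()]).
#' @param shared_fraction fraction of units per pool that also receive the
#'   drive of a pool of another DoF (multi-DoF units).
#' @param template_length MUAP support in samples.
#' @param kin_noise_deg RMS of the slow kinematic sensor noise added to the
#'   recorded angles (degrees; inertial motion capture reports nonzero,
#'   slowly varying output even at rest). The common drive derives from the
#'   noiseless cue; set 0 to disable.
#' @param seed master session seed; every random component derives from it.
#' @return a list of class `mu_session`: `emg`, `kin`, `seg`, `spikes`
#'   (ground truth), `spikes_dec`, `bank`, `pool` (combined), `config`, `id`.
#' @export
sim_session <- function(ramp_duration = 2.5, n_trials = 3L,
                        units_per_pool = 30L, grid_shape = c(8L, 8L),
                        snr_db = 15, corruption = NULL, rom = 60,
                        rest_duration = 2, sample_rate = 2048,
                        recruitment_range = 30, min_rate = 8, peak_rate = 35,
                        rate_gain = 30, isi_cov = 0.15,
                        shared_fraction = 0.05, template_length = 51L,
                        kin_noise_deg = 1.0, seed = 1L) {
  fs <- sample_rate
  set.seed(derive_seed(seed, "session"))
  dof_order <- sample(1:3)

  cues <- lapply(1:3, function(d)
    generate_cue(cue_profile(d, ramp_duration, n_trials, rom, rest_duration,
                             fs)))
  angles <- NULL; seg <- NULL; offset <- 0L
  for (d in dof_order) {
    cue <- cues[[d]]
    s <- as.data.frame(attr(cue, "segmentation"))
    s$start_sample <- as.integer(s$start_sample + offset)
    s$end_sample <- as.integer(s$end_sample + offset)
    seg <- rbind(seg, s)
    angles <- cbind(angles, cue$angles)
    offset <- offset + ncol(cue$angles)
  }
  cue_kin <- kinematics_trace(angles, fs) # noiseless cue drives the pools
  seg <- trial_segmentation(seg)
  n <- ncol(angles)

  # recorded kinematics: cue plus slow inertial sensor noise
  if (kin_noise_deg > 0) {
    set.seed(derive_seed(seed, "kin_noise"))
    knot_hz <- 2
    n_knots <- max(2L, ceiling(n / fs * knot_hz) + 1L)
    t_knot <- seq(0, n - 1, length.out = n_knots)
    sensor <- t(vapply(1:3, function(d)
      stats::approx(t_knot, stats::rnorm(n_knots, 0, kin_noise_deg),
                    xout = 0:(n - 1))$y, numeric(n)))
    kin <- kinematics_trace(angles + sensor, fs)
  } else kin <- cue_kin

  loci <- pool_loci(grid_shape)
  pool_defs <- data.frame(pool = 1:6, dof = rep(1:3, each = 2),
                          direction = rep(c(1, -1), 3))
  drives <- lapply(1:6, function(p)
    drive_from_kinematics(cue_kin, pool_defs$dof[p], pool_defs$direction[p],
                          rom))

  pools <- list(); banks <- list(); unit_pool <- integer(0)
  all_units <- list(); all_thr <- numeric(0); all_ids <- character(0)
  waveforms <- NULL; gains <- NULL; offsets <- integer(0)
  for (p in 1:6) {
    pl <- build_pool(units_per_pool, recruitment_range, min_rate, peak_rate,
                     rate_gain, isi_cov, grid_shape, center = loci[p, ],
                     seed = derive_seed(seed, paste0("pool", p)))
    pl$unit_ids <- sprintf("p%d_%s", p, pl$unit_ids)
    sp <- sample_spike_trains(pl, drives[[p]], fs,
                              seed = derive_seed(seed, paste0("spk", p)))
    names(sp$units) <- pl$unit_ids
    # multi-DoF units: a small fraction also receive another DoF's drive
    if (shared_fraction > 0) {
      set.seed(derive_seed(seed, paste0("share", p)))
      shared <- which(stats::runif(pl$n_units) < shared_fraction)
      for (j in shared) {
        other <- sample(which(pool_defs$dof != pool_defs$dof[p]), 1L)
        sub <- pl; sub$n_units <- 1L
        sub$unit_ids <- pl$unit_ids[j]
        sub$recruitment_thresholds <- pl$recruitment_thresholds[j]
        sp2 <- sample_spike_trains(sub, pmax(drives[[p]], drives[[other]]),
                                   fs, seed = derive_seed(
                                     seed, paste0("shspk", p, "_", j)))
        sp$units[[pl$unit_ids[j]]] <- sp2$units[[1L]]
      }
    }
    bk <- generate_templates(pl, grid_shape, template_length,
                             seed = derive_seed(seed, paste0("tmpl", p)))
    bk$unit_ids <- pl$unit_ids
    names(bk$offsets) <- pl$unit_ids
    all_units <- c(all_units, sp$units)
    all_thr <- c(all_thr, pl$recruitment_thresholds)
    all_ids <- c(all_ids, pl$unit_ids)
    unit_pool <- c(unit_pool, rep(p, pl$n_units))
    waveforms <- cbind(waveforms, bk$waveforms)
    gains <- cbind(gains, bk$gains)
    offsets <- c(offsets, bk$offsets)
    pools[[p]] <- pl
  }
  spikes <- spike_train_set(all_units, "ground_truth")
  bank <- muap_bank(all_ids, template_length, offsets, waveforms, gains)
  combined_pool <- list(n_units = length(all_ids), unit_ids = all_ids,
                        recruitment_thresholds = all_thr,
                        unit_pool = unit_pool, pool_defs = pool_defs)

  emg <- synthesize_emg(spikes, bank, fs, n, grid_shape, snr_db,
                        seed = derive_seed(seed, "emg"))
  spikes_dec <- if (is.null(corruption)) spikes else
    corrupt_spike_trains(spikes, corruption, combined_pool, n, fs,
                         seed = derive_seed(seed, "dec"))

  config <- list(ramp_duration = ramp_duration, n_trials = n_trials,
                 units_per_pool = units_per_pool,
                 grid_shape = as.integer(grid_shape), snr_db = snr_db,
                 corruption = if (is.null(corruption)) NULL else
                   unclass(corruption),
                 rom = rom, rest_duration = rest_duration, sample_rate = fs,
                 recruitment_range = recruitment_range, min_rate = min_rate,
                 peak_rate = peak_rate, rate_gain = rate_gain,
                 isi_cov = isi_cov, shared_fraction = shared_fraction,
                 template_length = template_length,
                 kin_noise_deg = kin_noise_deg, seed = seed)
  structure(list(emg = emg, kin = kin, seg = seg, spikes = spikes,
                 spikes_dec = spikes_dec, bank = bank, pool = combined_pool,
                 config = config,
                 id = paste0("sim-", seed, "-", ramp_duration, "-",
                             paste(grid_shape, collapse = "x"), "-",
                             units_per_pool, "-", snr_db, "-",
                             !is.null(corruption))),
            class = "mu_session")
}

#' @export
print.mu_session <- function(x, ...) {
  cat(sprintf(
    "<mu_session> %.3g s ramps, %d trials/DoF, %d units, %d x %d grid, %d samples @ %g Hz\n",
    x$config$ramp_duration, x$config$n_trials, x$pool$n_units,
    x$emg$grid_shape[1], x$emg$grid_shape[2], ncol(x$emg$samples),
    x$emg$sample_rate))
  cat(sprintf("  decomposed trains: %d units (%s)\n",
              length(x$spikes_dec$units), x$spikes_dec$provenance))
  invisible(x)
}
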