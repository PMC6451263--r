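# The wrist-kinematics decoder: one fitting function per feature set,
# returning a classed model object with the usual methods. All stage
# parameters (channel mask, thresholds, STA templates, PCA bases, unit-DoF
# assignments, robust linear maps, regression weights) are estimated on the
# training ramps only and applied unchanged at prediction time.

decoder_kinds <- c("TD", "AM1", "AM2", "PROPOSED")

#' Decoder stage parameters
#'
#' @param pca_variance cumulative explained-variance target for PCA bases.
#' @param min_cor minimum absolute unit-to-DoF assignment correlation for a
#'   unit to enter an activation pool.
#' @param a0 activation initialization, degrees (neutral wrist).
#' @param mask_factor RMS ratio for noisy-channel exclusion.
#' @param template_length STA template support, samples (25 ms at 2048 Hz).
#' @param min_spikes minimum usable discharges for a unit's STA template.
#' @export
decoder_control <- function(pca_variance = 0.98, min_cor = 0.2, a0 = 0,
                            mask_factor = 5, template_length = 51L,
                            min_spikes = 10L) {
  list(pca_variance = pca_variance, min_cor = min_cor, a0 = a0,
       mask_factor = mask_factor, template_length = template_length,
       min_spikes = min_spikes)
}

#' Per-trial sample spans of a session
#'
#' Partitions `[0, n_samples)` into one span per trial: boundaries lie at the
#' midpoints of the rests between consecutive trials (rest periods are part
#' of both training and testing traces).
#'
#' @param seg a [trial_segmentation()].
#' @param n_samples session length.
#' @return data.frame `trial_id`, `dof`, `start`, `end` (0-based half-open).
#' @export
trial_spans <- function(seg, n_samples) {
  s <- as.data.frame(seg)
  tr <- do.call(rbind, lapply(split(s, s$trial_id), function(d)
    data.frame(trial_id = d$trial_id[1L], dof = d$dof[1L],
               first = min(d$start_sample), last = max(d$end_sample))))
  tr <- tr[order(tr$first), ]
  k <- nrow(tr)
  bounds <- c(0L, if (k > 1L)
    as.integer(floor((tr$last[-k] + tr$first[-1L]) / 2)), as.integer(n_samples))
  data.frame(trial_id = tr$trial_id, dof = tr$dof,
             start = bounds[-(k + 1L)], end = bounds[-1L],
             row.names = NULL)
}

# Precompute the fold-independent parts of a session: band-passed EMG,
# windows, window-averaged targets, full DSC matrix, trial spans.
prepare_session <- function(session, window = window_spec()) {
  if (!is.null(session$prep) &&
      identical(session$prep$window, window)) return(session)
  emg <- session$emg
  n <- ncol(emg$samples)
  fs <- emg$sample_rate
  filt <- bandpass(emg)
  win <- segment_windows(n, window, fs)
  ws <- window_samples(window, fs)$window
  # window-averaged angle targets, computed per window so that a window's
  # target depends only on its own samples
  idx <- outer(seq_len(ws), win$start, "+")
  targets <- vapply(1:3, function(d)
    colMeans(matrix(session$kin$angles[d, idx], ws)), numeric(nrow(win)))
  dsc <- spike_counts(session$spikes_dec, window, n, fs)
  spans <- trial_spans(session$seg, n)
  centers <- (win$start + win$end) / 2
  wt <- rep(NA_character_, nrow(win))
  for (k in seq_len(nrow(spans)))
    wt[centers >= spans$start[k] & centers < spans$end[k]] <-
      spans$trial_id[k]
  ep <- span_mask(data.frame(start = session$seg$start_sample,
                             end = session$seg$end_sample), n)
  session$prep <- list(window = window, filt = filt, win = win,
                       targets = targets, dsc = dsc, spans = spans,
                       win_trial = wt, episode_mask = ep, n = n, fs = fs)
  session
}

mask_channels_rms <- function(x, factor) {
  r <- sqrt(rowMeans(x^2))
  med <- stats::median(r)
  bad <- r > factor * med | r < med / factor
  if (all(bad)) stop_mukin("degenerate_input", "all channels masked")
  bad
}

restrict_spikes <- function(spikes, spans) {
  units <- lapply(spikes$units, function(sp) sp[in_spans(sp, spans)])
  spike_train_set(units, spikes$provenance)
}

# Fit decoders for several feature sets on one training split, sharing the
# expensive stage computations (filtering, STA, reconstruction, residual).
fit_fold <- function(session, train_trials, kinds = decoder_kinds,
                     window = window_spec(), control = decoder_control()) {
  session <- prepare_session(session, window)
  prep <- session$prep
  kinds <- match.arg(kinds, decoder_kinds, several.ok = TRUE)
  n <- prep$n; fs <- prep$fs
  train_rows <- which(prep$win_trial %in% train_trials)
  if (length(train_rows) < 2L)
    stop_mukin("invalid_input", "not enough training windows")
  tr_spans <- prep$spans[prep$spans$trial_id %in% train_trials, , drop = FALSE]
  tr_mask <- span_mask(data.frame(start = tr_spans$start, end = tr_spans$end),
                       n)
  bad <- mask_channels_rms(prep$filt$samples[, tr_mask, drop = FALSE],
                           control$mask_factor)
  filt <- emg_recording(prep$filt$samples, fs, prep$filt$grid_shape, bad)
  rest_idx0 <- which(tr_mask & !prep$episode_mask) - 1L
  thresholds <- estimate_td_thresholds(filt, rest_idx0)
  targets_tr <- prep$targets[train_rows, , drop = FALSE]

  base <- list(window = window, fs = fs, channel_mask = bad,
               thresholds = thresholds, control = control,
               train_trials = train_trials, session_id = session$id,
               win = prep$win, win_trial = prep$win_trial,
               targets = prep$targets, unit_ids = colnames(prep$dsc))
  out <- list()

  if ("TD" %in% kinds) {
    td_all <- extract_td(filt, window, thresholds)
    basis <- fit_pca(td_all[train_rows, , drop = FALSE],
                     control$pca_variance)
    feats <- apply_pca(basis, td_all)
    out$TD <- c(base, list(kind = "TD", pca = basis, features = feats,
                           coef = fit_linear(feats[train_rows, , drop = FALSE],
                                             targets_tr)))
  }

  neural_kinds <- intersect(kinds, c("AM1", "AM2", "PROPOSED"))
  if (length(neural_kinds)) {
    dsc <- prep$dsc
    need_resid <- any(c("AM1", "PROPOSED") %in% neural_kinds)
    bank <- NULL; res_td <- NULL; res_thr <- NULL
    active <- which(!bad)
    if (need_resid) {
      emg_act <- emg_recording(filt$samples[active, , drop = FALSE], fs,
                               c(1L, length(active)))
      spikes_tr <- restrict_spikes(session$spikes_dec, tr_spans)
      bank <- sta_bank(emg_act, spikes_tr, control$template_length,
                       min_spikes = control$min_spikes)
      recon <- reconstruct_emg(session$spikes_dec, bank, n, fs,
                               c(1L, length(active)))
      resid <- residual_emg(emg_act, recon)
      res_thr <- estimate_td_thresholds(resid, rest_idx0)
      res_td <- extract_td(resid, window, res_thr)
    }
    if ("AM2" %in% neural_kinds) {
      basis <- fit_pca(dsc[train_rows, , drop = FALSE], control$pca_variance)
      feats <- apply_pca(basis, dsc)
      out$AM2 <- c(base, list(kind = "AM2", pca = basis, features = feats,
                              coef = fit_linear(
                                feats[train_rows, , drop = FALSE],
                                targets_tr)))
    }
    if ("AM1" %in% neural_kinds) {
      joint <- cbind(dsc, res_td)
      basis <- fit_pca(joint[train_rows, , drop = FALSE],
                       control$pca_variance)
      feats <- apply_pca(basis, joint)
      out$AM1 <- c(base, list(kind = "AM1", pca = basis, bank = bank,
                              res_thresholds = res_thr, features = feats,
                              coef = fit_linear(
                                feats[train_rows, , drop = FALSE],
                                targets_tr)))
    }
    if ("PROPOSED" %in% neural_kinds) {
      assignment <- assign_dof(dsc[train_rows, , drop = FALSE], targets_tr)
      keep <- !is.na(assignment$dof) &
        abs(assignment$correlation) >= control$min_cor
      # g is fitted on the windows where the assigned DoF is active (its
      # training ramp episodes): there the count-zero windows of the
      # antagonist direction carry high angle variance, so the bisquare
      # rejects them as outliers instead of locking onto the rest cluster
      seg_df <- as.data.frame(session$seg)
      centers <- (prep$win$start + prep$win$end) / 2
      g_list <- list()
      for (d in 1:3) {
        eps <- seg_df[seg_df$dof == d &
                        seg_df$trial_id %in% train_trials, , drop = FALSE]
        on_d <- in_spans(centers, data.frame(start = eps$start_sample,
                                             end = eps$end_sample))
        rows_d <- intersect(train_rows, which(on_d))
        for (id in assignment$unit_id[keep & assignment$dof == d]) {
          g <- tryCatch(fit_g(dsc[rows_d, id], prep$targets[rows_d, d]),
                        mukin_error = function(e) NULL)
          if (!is.null(g)) g_list[[id]] <- g
        }
      }
      act <- compute_activations(dsc, assignment, g_list, control$a0,
                                 control$min_cor)
      res_basis <- fit_pca(res_td[train_rows, , drop = FALSE],
                           control$pca_variance)
      feats <- neural_feature_matrix(act, apply_pca(res_basis, res_td))
      out$PROPOSED <- c(base, list(kind = "PROPOSED", assignment = assignment,
                                   g_list = g_list, bank = bank,
                                   res_thresholds = res_thr,
                                   res_pca = res_basis, features = feats,
                                   coef = fit_linear(
                                     feats[train_rows, , drop = FALSE],
                                     targets_tr)))
    }
  }
  lapply(out, function(d) structure(d, class = "mu_decoder"))
}

#' Fit a wrist-kinematics decoder on a session
#'
#' Fits one of the four compared feature pipelines end to end on the training
#' trials of a session and returns a model object that maps windowed EMG /
#' spike-train features to the three wrist joint angles through ordinary
#' least squares:
#'
#' * `"TD"` — interference-EMG time-domain features (RMS, SSC, ZC, WL per
#'   channel) with PCA retaining 98% variance;
#' * `"AM2"` — decomposed spike counts (DSC) with PCA;
#' * `"AM1"` — DSC plus residual-EMG TD features with one joint PCA;
#' * `"PROPOSED"` — the model-based dimensionality reduction: per-DoF
#'   median-pooled activations from robustly fitted per-unit linear maps,
#'   plus PCA-reduced residual-EMG TD features.
#'
#' All stage parameters are estimated on the training trials only; the
#' regression weights are fixed after training.
#'
#' @param session an `mu_session` (see [sim_session()], [read_session()]).
#' @param kind feature set, one of `"TD"`, `"AM1"`, `"AM2"`, `"PROPOSED"`.
#' @param train_trials character vector of training trial ids (default: all
#'   trials in the session).
#' @param window a [window_spec()].
#' @param control a [decoder_control()]-style list of stage parameters.
#' @return an object of class `mu_decoder`.
#' @seealso [predict.mu_decoder()], [run_comparison()]
#' @export
fit_decoder <- function(session, kind = "PROPOSED", train_trials = NULL,
                        window = window_spec(),
                        control = decoder_control()) {
  kind <- match.arg(kind, decoder_kinds)
  session <- prepare_session(session, window)
  train_trials <- train_trials %||% unique(session$prep$spans$trial_id)
  fit_fold(session, train_trials, kind, window, control)[[kind]]
}

# Recompute the decoder's feature matrix on a (new) prepared session using
# only parameters stored at training time.
decoder_features <- function(object, session) {
  session <- prepare_session(session, object$window)
  prep <- session$prep
  filt <- emg_recording(prep$filt$samples, prep$fs, prep$filt$grid_shape,
                        object$channel_mask)
  if (object$kind == "TD") {
    td <- extract_td(filt, object$window, object$thresholds)
    return(apply_pca(object$pca, td))
  }
  dsc <- spike_counts(session$spikes_dec, object$window, prep$n, prep$fs)
  # align unit columns with the training session (absent units count zero)
  full <- matrix(0L, nrow(dsc), length(object$unit_ids),
                 dimnames = list(NULL, object$unit_ids))
  shared <- intersect(colnames(dsc), object$unit_ids)
  full[, shared] <- dsc[, shared]
  dsc <- full
  if (object$kind == "AM2") return(apply_pca(object$pca, dsc))
  active <- which(!object$channel_mask)
  emg_act <- emg_recording(filt$samples[active, , drop = FALSE], prep$fs,
                           c(1L, length(active)))
  recon <- reconstruct_emg(session$spikes_dec, object$bank, prep$n, prep$fs,
                           c(1L, length(active)))
  resid <- residual_emg(emg_act, recon)
  res_td <- extract_td(resid, object$window, object$res_thresholds)
  if (object$kind == "AM1")
    return(apply_pca(object$pca, cbind(dsc, res_td)))
  act <- compute_activations(dsc, object$assignment, object$g_list,
                             object$control$a0, object$control$min_cor)
  neural_feature_matrix(act, apply_pca(object$res_pca, res_td))
}

# OLS with intercept; rank-deficient designs fall back to the minimum-norm
# solution with a warning.
fit_linear <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_mukin("invalid_input", "misaligned windows")
  Xa <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xa)
  if (qrx$rank == ncol(Xa)) {
    coef <- qr.coef(qrx, Y)
  } else {
    warning("rank-deficient design; using minimum-norm solution")
    sv <- svd(Xa)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    rownames(coef) <- colnames(Xa)
  }
  coef
}

#' Predict wrist joint angles from a fitted decoder
#'
#' Applies the fixed training-time pipeline and regression weights to the
#' requested trials of a session, optionally smoothing each DoF with the
#' median of three consecutive outputs (the final-estimate rule).
#'
#' @param object an `mu_decoder`.
#' @param session a session; defaults to the training session (cached
#'   features are reused when the id matches).
#' @param trials trial ids to predict (default: all windows).
#' @param smooth apply the three-sample running median (default TRUE).
#' @param ... unused.
#' @return windows x 3 matrix of angle estimates (degrees), with attribute
#'   `"rows"` giving the window indices used.
#' @export
predict.mu_decoder <- function(object, session = NULL, trials = NULL,
                               smooth = TRUE, ...) {
  if (is.null(session) || identical(session$id, object$session_id)) {
    feats <- object$features
    wt <- object$win_trial
  } else {
    feats <- decoder_features(object, session)
    session <- prepare_session(session, object$window)
    wt <- session$prep$win_trial
  }
  rows <- if (is.null(trials)) seq_len(nrow(feats)) else which(wt %in% trials)
  if (ncol(feats) != nrow(object$coef) - 1L)
    stop_mukin("invalid_input", "feature dimension mismatch")
  yhat <- cbind(1, feats[rows, , drop = FALSE]) %*% object$coef
  if (smooth) yhat <- median3(yhat)
  colnames(yhat) <- paste0("dof", 1:3)
  attr(yhat, "rows") <- rows
  yhat
}

#' @export
print.mu_decoder <- function(x, ...) {
  cat(sprintf("<mu_decoder> kind=%s, %d features -> 3 DoF, trained on %d trials\n",
              x$kind, nrow(x$coef) - 1L, length(x$train_trials)))
  if (!is.null(x$pca))
    cat(sprintf("  PCA: %d components (%.1f%% variance)\n", x$pca$retained,
                100 * sum(x$pca$explained[seq_len(x$pca$retained)])))
  if (!is.null(x$g_list))
    cat(sprintf("  activation model: %d units across pools (%s)\n",
                length(x$g_list),
                paste(table(x$assignment$dof[!is.na(x$assignment$dof)]),
                      collapse = "/")))
  invisible(x)
}

#' @export
summary.mu_decoder <- function(object, ...) {
  pred <- predict(object, smooth = TRUE)
  rows <- attr(pred, "rows")
  r2 <- r_squared(pred, object$targets[rows, , drop = FALSE])
  out <- list(kind = object$kind, n_features = nrow(object$coef) - 1L,
              n_channels = sum(!object$channel_mask),
              train_trials = object$train_trials, r2_train = r2)
  class(out) <- "summary.mu_decoder"
  out
}

#' @export
print.summary.mu_decoder <- function(x, ...) {
  cat(sprintf("Decoder (%s): %d features, %d channels\n", x$kind,
              x$n_features, x$n_channels))
  cat(sprintf("Training trials: %s\n", paste(x$train_trials, collapse = ", ")))
  cat(sprintf("Training-trace R^2 per DoF: %s (mean %.3f)\n",
              paste(sprintf("%.3f", x$r2_train$per_dof), collapse = ", "),
              x$r2_train$mean))
  invisible(x)
}

#' @export
coef.mu_decoder <- function(object, ...) object$coef

#' @export
residuals.mu_decoder <- function(object, ...) {
  pred <- predict(object, smooth = FALSE)
  object$targets - pred
}

#' Plot decoder estimates against recorded kinematics
#'
#' @param x an `mu_decoder`.
#' @param session optional session (defaults to the training session cache).
#' @param trials trial ids to display.
#' @param dofs DoFs to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mu_decoder <- function(x, session = NULL, trials = NULL, dofs = 1:3,
                            ...) {
  pred <- predict(x, session, trials)
  rows <- attr(pred, "rows")
  truth <- x$targets[rows, , drop = FALSE]
  old <- graphics::par(mfrow = c(length(dofs), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (d in dofs) {
    graphics::matplot(cbind(truth[, d], pred[, d]), type = "l",
                      lty = c(1, 2), col = c("black", "red"),
                      ylab = sprintf("DoF %d (deg)", d), xlab = "", ...)
  }
  invisible(x)
}
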