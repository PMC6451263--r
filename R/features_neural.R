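# Neural feature sets: windowed decomposed spike counts (DSC), cross-trial
# unit matching by template cross-correlation, spike-triggered-average MUAP
# estimation, EMG reconstruction and residual-EMG features.

#' Windowed decomposed spike counts (DSC)
#'
#' Counts discharges per unit in each half-open window `[start, end)` of the
#' shared analysis windowing.
#'
#' @param spikes a [spike_train_set()].
#' @param spec a [window_spec()].
#' @param n_samples trace length.
#' @param fs sampling rate, Hz.
#' @return integer matrix windows x units with unit ids as column names and
#'   attribute `"window_end_sample"`.
#' @export
spike_counts <- function(spikes, spec, n_samples, fs) {
  win <- segment_windows(n_samples, spec, fs)
  sp_all <- unlist(spikes$units, use.names = FALSE)
  if (length(sp_all) && any(sp_all >= n_samples))
    stop_mukin("invalid_input", "spike index beyond trace length")
  out <- matrix(0L, nrow(win), length(spikes$units),
                dimnames = list(NULL, names(spikes$units)))
  for (id in names(spikes$units)) {
    sp <- spikes$units[[id]]
    if (!length(sp)) next
    out[, id] <- findInterval(win$end - 1L, sp) -
      findInterval(win$start - 1L, sp)
  }
  attr(out, "window_end_sample") <- win$end
  out
}

#' Spike-triggered average MUAP template
#'
#' Averages EMG segments `[t - offset, t - offset + template_length)` over a
#' unit's discharges `t`; discharges whose support exceeds the signal bounds
#' are skipped.
#'
#' @param emg an [emg_recording()].
#' @param spike_idx0 0-based discharge sample indices.
#' @param template_length template support, samples.
#' @param offset 0-based alignment sample within the template that the
#'   discharge marks (default: centre).
#' @param min_spikes minimum usable discharges (default 10).
#' @return channels x template_length matrix with attributes `"offset"` and
#'   `"n_spikes"`.
#' @export
spike_triggered_average <- function(emg, spike_idx0, template_length = 51L,
                                    offset = (template_length - 1L) %/% 2L,
                                    min_spikes = 10L) {
  L <- as.integer(template_length)
  n <- ncol(emg$samples)
  starts0 <- spike_idx0 - offset
  starts0 <- starts0[starts0 >= 0L & (starts0 + L) <= n]
  if (length(starts0) < min_spikes)
    stop_mukin("insufficient_data", sprintf(
      "only %d usable discharges (need %d)", length(starts0), min_spikes))
  C <- nrow(emg$samples)
  idx <- as.vector(outer(seq_len(L), starts0, "+")) # 1-based
  arr <- array(emg$samples[, idx], dim = c(C, L, length(starts0)))
  tmpl <- rowMeans(arr, dims = 2L)
  attr(tmpl, "offset") <- as.integer(offset)
  attr(tmpl, "n_spikes") <- length(starts0)
  tmpl
}

#' Estimate a template bank by spike-triggered averaging
#'
#' @param emg an [emg_recording()].
#' @param spikes a [spike_train_set()]; units with fewer than `min_spikes`
#'   usable discharges are omitted from the bank.
#' @param template_length,offset,min_spikes see
#'   [spike_triggered_average()].
#' @return a [muap_bank()] with full per-unit templates.
#' @export
sta_bank <- function(emg, spikes, template_length = 51L,
                     offset = (template_length - 1L) %/% 2L,
                     min_spikes = 10L) {
  tmpls <- list()
  for (id in names(spikes$units)) {
    t <- tryCatch(
      spike_triggered_average(emg, spikes$units[[id]], template_length,
                              offset, min_spikes),
      mukin_error = function(e) NULL)
    if (!is.null(t)) tmpls[[id]] <- t
  }
  if (!length(tmpls))
    stop_mukin("insufficient_data", "no unit had enough discharges")
  muap_bank(unit_ids = names(tmpls), template_length = template_length,
            offsets = rep(offset, length(tmpls)), templates = tmpls)
}

shift_rows <- function(m, lag) {
  # shift each row by lag samples (positive = delay), zero fill
  L <- ncol(m)
  out <- matrix(0, nrow(m), L)
  if (lag >= 0) {
    if (lag < L) out[, (1L + lag):L] <- m[, 1L:(L - lag), drop = FALSE]
  } else {
    if (-lag < L) out[, 1L:(L + lag)] <- m[, (1L - lag):L, drop = FALSE]
  }
  out
}

#' Match motor units across template banks
#'
#' For each unit pair, templates are compared on the channels where either
#' waveform's peak absolute amplitude exceeds the baseline noise SD by 25%
#' (factor `channel_rule`); the admissible channels are concatenated and the
#' normalized cross-correlation is evaluated over lags of up to half the
#' template length, reporting the signed value at the lag of maximal
#' magnitude (so shape-inverted templates report their negative correlation
#' rather than an incidental positive side-lobe). Pairs with correlation
#' above `match_threshold` are deemed the same unit; the merged registry is
#' the transitive closure over matched pairs (processed in order of
#' decreasing correlation).
#'
#' @param bank_a,bank_b [muap_bank()] objects with equal template lengths.
#' @param noise_sd per-channel baseline noise SD.
#' @param match_threshold correlation threshold (default 0.8).
#' @param channel_rule peak/noise ratio for channel admission (default 1.25).
#' @return list with `pairs` (data.frame `unit_a`, `unit_b`, `correlation`,
#'   `n_channels`, `matched`, `reason`) and `registry` (list of merged unit id
#'   groups).
#' @export
match_units <- function(bank_a, bank_b, noise_sd, match_threshold = 0.8,
                        channel_rule = 1.25) {
  if (bank_a$template_length != bank_b$template_length)
    stop_mukin("invalid_input", "template lengths differ")
  L <- bank_a$template_length
  max_lag <- L %/% 2L
  rows <- list()
  for (ia in bank_a$unit_ids) for (ib in bank_b$unit_ids) {
    ta <- bank_template(bank_a, ia)
    tb <- bank_template(bank_b, ib)
    peak <- pmax(apply(abs(ta), 1L, max), apply(abs(tb), 1L, max))
    adm <- which(peak > channel_rule * noise_sd)
    if (!length(adm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit_a = ia, unit_b = ib, correlation = NA_real_, n_channels = 0L,
        matched = FALSE, reason = "no_admissible_channels")
      next
    }
    va <- as.vector(ta[adm, , drop = FALSE])
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(tb[adm, ]^2))
    best <- 0
    for (lag in -max_lag:max_lag) {
      vb <- as.vector(shift_rows(tb[adm, , drop = FALSE], lag))
      r <- sum(va * vb) / (na * nb)
      if (abs(r) > abs(best)) best <- r
    }
    rows[[length(rows) + 1L]] <- data.frame(
      unit_a = ia, unit_b = ib, correlation = best,
      n_channels = length(adm), matched = best > match_threshold,
      reason = "")
  }
  pairs <- do.call(rbind, rows)
  # transitive closure via union-find, highest correlations first
  ids <- unique(c(paste0("a:", bank_a$unit_ids), paste0("b:", bank_b$unit_ids)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  m <- pairs[pairs$matched %in% TRUE, , drop = FALSE]
  m <- m[order(-m$correlation), , drop = FALSE]
  for (k in seq_len(nrow(m)))
    parent[[find(paste0("a:", m$unit_a[k]))]] <-
      find(paste0("b:", m$unit_b[k]))
  roots <- vapply(ids, find, "")
  registry <- unname(split(ids, roots))
  list(pairs = pairs, registry = registry)
}

#' Reconstruct EMG from spike trains and templates
#'
#' Superposition of each unit's template at its discharge indices using the
#' bank's alignment offsets (the same placement convention as
#' spike-triggered averaging).
#'
#' @param spikes a [spike_train_set()].
#' @param bank a [muap_bank()].
#' @param n_samples trace length.
#' @param fs sampling rate, Hz (carried onto the result).
#' @param grid_shape grid of the output recording.
#' @param require_all error if a firing unit lacks a template (default FALSE:
#'   units without templates contribute nothing, as after insufficient-data
#'   STA).
#' @export
reconstruct_emg <- function(spikes, bank, n_samples, fs,
                            grid_shape = NULL, require_all = FALSE) {
  ids <- names(spikes$units)
  have <- ids %in% bank$unit_ids
  if (require_all && !all(have | lengths(spikes$units) == 0L))
    stop_mukin("missing_template",
               paste("no template for unit(s):",
                     paste(ids[!have], collapse = ", ")))
  C <- if (!is.null(bank$templates))
    nrow(bank$templates[[1L]]) else nrow(bank$gains)
  grid_shape <- grid_shape %||% c(1L, C)
  out <- matrix(0, C, n_samples)
  for (id in ids[have]) {
    sp <- spikes$units[[id]]
    if (!length(sp)) next
    tmpl <- bank_template(bank, id)
    ov <- overlay_template_matrix(sp - bank$offsets[[id]], tmpl, n_samples)
    if (length(ov$cols))
      out[, ov$cols] <- out[, ov$cols] + ov$block
  }
  emg_recording(out, fs, grid_shape)
}

#' Residual EMG
#'
#' The recorded EMG minus the part explained by the decomposed spike trains.
#'
#' @param emg recorded [emg_recording()].
#' @param reconstruction reconstructed [emg_recording()] of the same shape.
#' @export
residual_emg <- function(emg, reconstruction) {
  if (!all(dim(emg$samples) == dim(reconstruction$samples)))
    stop_mukin("invalid_input", "shape mismatch")
  emg_recording(emg$samples - reconstruction$samples, emg$sample_rate,
                emg$grid_shape, emg$bad_channel_mask)
}

#' Assemble a comparison neural feature set
#'
#' `AM1` concatenates DSC and residual-EMG TD features and applies one joint
#' PCA; `AM2` applies PCA to the DSC alone; `DSC` returns the raw count
#' matrix (the input representation of the model-based dimensionality
#' reduction).
#'
#' @param kind one of `"AM1"`, `"AM2"`, `"DSC"`.
#' @param dsc windows x units count matrix.
#' @param residual_td windows x features residual TD matrix (AM1 only).
#' @param pca_variance retained-variance target.
#' @param basis optional previously fitted [fit_pca()] basis (training-fold
#'   basis applied unchanged to test data).
#' @return feature matrix with attribute `"basis"` (for PCA kinds).
#' @export
assemble_feature_set <- function(kind = c("AM1", "AM2", "DSC"), dsc,
                                 residual_td = NULL, pca_variance = 0.98,
                                 basis = NULL) {
  kind <- match.arg(kind)
  if (kind == "DSC") return(dsc)
  m <- if (kind == "AM2") dsc else {
    if (is.null(residual_td))
      stop_mukin("invalid_input", "AM1 requires residual TD features")
    if (nrow(residual_td) != nrow(dsc))
      stop_mukin("invalid_input", "window-count mismatch")
    cbind(dsc, residual_td)
  }
  if (is.null(basis)) basis <- fit_pca(m, pca_variance)
  out <- apply_pca(basis, m)
  attr(out, "basis") <- basis
  out
}
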