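# Interference-EMG preprocessing and time-domain feature extraction.
#
# The classic myocontrol feature set: per 100 ms window (90 ms step) and per
# channel, root mean square (RMS), slope sign changes (SSC), zero crossings
# (ZC) and waveform length (WL), followed by PCA retaining 98% of the
# variance.

#' Sliding analysis window specification
#'
#' Defaults follow the standard myocontrol windowing: 100 ms windows advanced
#' every 90 ms (10 ms overlap). Sample counts are `round(seconds * fs)`:
#' 205 and 184 samples at 2048 Hz.
#'
#' @param window_length window length, seconds.
#' @param step step between window starts, seconds.
#' @export
window_spec <- function(window_length = 0.100, step = 0.090) {
  if (window_length <= 0 || step <= 0)
    stop_mukin("invalid_configuration", "window and step must be positive")
  structure(list(window_length = window_length, step = step),
            class = "window_spec")
}

window_samples <- function(spec, fs) {
  ws <- round(spec$window_length * fs)
  ss <- round(spec$step * fs)
  if (ws < 2) stop_mukin("invalid_configuration", "window must be >= 2 samples")
  list(window = as.integer(ws), step = as.integer(ss))
}

#' Enumerate sliding windows over a trace
#'
#' Windows are half-open 0-based sample intervals `[start, end)`; the count is
#' `floor((n_samples - window) / step) + 1` and a trailing partial window is
#' discarded. Returns an empty frame when the trace is shorter than one
#' window.
#'
#' @param n_samples trace length.
#' @param spec a [window_spec()].
#' @param fs sampling rate, Hz.
#' @return data.frame with columns `start`, `end` (0-based).
#' @export
segment_windows <- function(n_samples, spec, fs) {
  w <- window_samples(spec, fs)
  if (n_samples < w$window)
    return(data.frame(start = integer(0), end = integer(0)))
  starts <- seq.int(0L, n_samples - w$window, by = w$step)
  data.frame(start = starts, end = starts + w$window)
}

#' Zero-phase band-pass filter
#'
#' 5th-order Butterworth high-pass and low-pass cascade applied
#' forward-backward (zero phase), removing DC and content outside the
#' 20-500 Hz surface-EMG band.
#'
#' @param emg an [emg_recording()].
#' @param band `(low, high)` cutoffs in Hz.
#' @param order filter prototype order.
#' @export
bandpass <- function(emg, band = c(20, 500), order = 5L) {
  fs <- emg$sample_rate
  if (band[2] >= fs / 2)
    stop_mukin("invalid_configuration",
               "upper cutoff must be below the Nyquist frequency")
  if (band[1] <= 0 || band[1] >= band[2])
    stop_mukin("invalid_configuration", "invalid band edges")
  hp <- signal::butter(order, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(order, band[2] / (fs / 2), type = "low")
  x <- emg$samples
  for (ch in seq_len(nrow(x))) {
    v <- signal::filtfilt(hp, x[ch, ])
    x[ch, ] <- signal::filtfilt(lp, v)
  }
  emg_recording(x, fs, emg$grid_shape, emg$bad_channel_mask)
}

#' Mask channels with outlying RMS
#'
#' Channels whose RMS deviates from the median channel RMS by more than
#' `factor` in either direction are marked bad (the mask is recorded on the
#' returned recording; samples are untouched).
#'
#' @param emg an [emg_recording()].
#' @param factor allowed RMS ratio to the median channel (default 5).
#' @export
exclude_channels <- function(emg, factor = 5) {
  r <- sqrt(rowMeans(emg$samples^2))
  med <- stats::median(r)
  bad <- emg$bad_channel_mask | r > factor * med | r < med / factor
  if (all(bad))
    stop_mukin("degenerate_input", "all channels masked")
  emg_recording(emg$samples, emg$sample_rate, emg$grid_shape, bad)
}

#' Root mean square of a window
#' @param window numeric vector (non-empty).
#' @export
rms_value <- function(window) {
  if (!length(window)) stop_mukin("invalid_input", "empty window")
  sqrt(mean(window^2))
}

#' Zero crossings of a window
#'
#' Counts consecutive pairs with opposite signs whose absolute difference is
#' at least `threshold` (amplitude gate against noise-induced crossings).
#'
#' @param window numeric vector.
#' @param threshold nonnegative amplitude threshold, signal units.
#' @export
zero_crossings <- function(window, threshold = 0) {
  if (threshold < 0) stop_mukin("invalid_input", "threshold must be >= 0")
  n <- length(window)
  if (n < 2L) return(0L)
  a <- window[-n]; b <- window[-1L]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' Slope sign changes of a window
#'
#' Counts interior samples where `(x_k - x_{k-1}) * (x_k - x_{k+1})` is at
#' least `threshold` (threshold in squared-signal units).
#'
#' @param window numeric vector of length >= 3.
#' @param threshold nonnegative threshold, squared signal units.
#' @export
slope_sign_changes <- function(window, threshold = 0) {
  if (threshold < 0) stop_mukin("invalid_input", "threshold must be >= 0")
  n <- length(window)
  if (n < 3L) stop_mukin("invalid_input", "window must have >= 3 samples")
  x <- window
  a <- x[2:(n - 1L)] - x[1:(n - 2L)]
  b <- x[2:(n - 1L)] - x[3:n]
  sum(a * b >= threshold & a * b > 0)
}

#' Waveform length of a window
#' @param window numeric vector of length >= 2.
#' @export
waveform_length <- function(window) {
  if (length(window) < 2L)
    stop_mukin("invalid_input", "window must have >= 2 samples")
  sum(abs(diff(window)))
}

#' Estimate ZC/SSC thresholds from rest-period signal
#'
#' Per channel, `zc = min(3 * sigma_hat, 0.1 * full_scale)` with
#' `sigma_hat = 1.4826 * MAD` of the rest-period samples, and
#' `ssc = zc^2` (squared-signal units). An automated surrogate for the
#' manually chosen per-subject thresholds of standard practice, respecting
#' the usual bound of 10% of the full signal scale.
#'
#' @param emg an [emg_recording()] (typically band-passed).
#' @param rest_idx0 0-based sample indices of rest periods.
#' @return list with numeric per-channel vectors `zc` and `ssc`.
#' @export
estimate_td_thresholds <- function(emg, rest_idx0) {
  x <- emg$samples
  full_scale <- apply(abs(x), 1L, max)
  sig <- apply(x[, rest_idx0 + 1L, drop = FALSE], 1L, stats::mad)
  zc <- pmin(3 * sig, 0.1 * full_scale)
  list(zc = zc, ssc = zc^2)
}

#' Extract windowed time-domain features
#'
#' Per window and active (unmasked) channel: RMS, SSC, ZC, WL, ordered
#' channel-major. Column labels are `chXX_rms` etc.; the window end sample of
#' each row is stored in attribute `"window_end_sample"`.
#'
#' @param emg an [emg_recording()] (band-passed; masked channels are skipped).
#' @param spec a [window_spec()].
#' @param thresholds optional list as from [estimate_td_thresholds()]
#'   (defaults to zero thresholds).
#' @return numeric matrix windows x (4 * active channels) with attributes
#'   `"window_end_sample"` and `"labels"`.
#' @export
extract_td <- function(emg, spec = window_spec(), thresholds = NULL) {
  fs <- emg$sample_rate
  win <- segment_windows(ncol(emg$samples), spec, fs)
  ws <- window_samples(spec, fs)$window
  active <- which(!emg$bad_channel_mask)
  zc_thr <- thresholds$zc %||% rep(0, nrow(emg$samples))
  ssc_thr <- thresholds$ssc %||% rep(0, nrow(emg$samples))
  n_win <- nrow(win)
  out <- matrix(0, n_win, 4L * length(active))
  labels <- character(4L * length(active))
  if (n_win > 0L) {
    idx <- outer(seq_len(ws), win$start, "+") # ws x n_win, 1-based
    for (k in seq_along(active)) {
      ch <- active[k]
      X <- matrix(emg$samples[ch, idx], ws, n_win)
      rms <- sqrt(colMeans(X^2))
      d <- X[-1L, , drop = FALSE] - X[-ws, , drop = FALSE]
      wl <- colSums(abs(d))
      zc <- colSums(X[-1L, , drop = FALSE] * X[-ws, , drop = FALSE] < 0 &
                      abs(d) >= zc_thr[ch])
      a <- X[2:(ws - 1L), , drop = FALSE] - X[1:(ws - 2L), , drop = FALSE]
      b <- X[2:(ws - 1L), , drop = FALSE] - X[3:ws, , drop = FALSE]
      p <- a * b
      ssc <- colSums(p >= ssc_thr[ch] & p > 0)
      out[, (4L * k - 3L):(4L * k)] <- cbind(rms, ssc, zc, wl)
    }
  }
  for (k in seq_along(active))
    labels[(4L * k - 3L):(4L * k)] <-
      sprintf("ch%02d_%s", active[k], c("rms", "ssc", "zc", "wl"))
  colnames(out) <- labels
  attr(out, "window_end_sample") <- win$end
  attr(out, "labels") <- labels
  out
}

#' Fit a variance-retaining PCA basis
#'
#' Features are z-scored with training-set statistics (constant features get
#' unit scale and contribute nothing), then the smallest number of principal
#' components whose cumulative explained variance reaches `variance` is
#' retained.
#'
#' @param x training feature matrix (rows = windows).
#' @param variance cumulative explained-variance target (default 0.98).
#' @param standardize z-score features before PCA (default TRUE).
#' @return object of class `pca_basis` with fields `center`, `scale`,
#'   `rotation`, `retained`, `explained` (all components' variance fractions).
#' @export
fit_pca <- function(x, variance = 0.98, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_mukin("invalid_input", "need at least 2 rows")
  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0)
    stop_mukin("degenerate_input", "feature matrix has zero variance")
  frac <- ev / tot
  k <- which(cumsum(frac) >= variance - 1e-12)[1L]
  if (is.na(k)) k <- length(frac)
  structure(list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 retained = k, explained = frac, variance_target = variance),
            class = "pca_basis")
}

#' Project features onto a fitted PCA basis
#' @param basis a [fit_pca()] result. @param x feature matrix.
#' @export
apply_pca <- function(basis, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(basis$center))
    stop_mukin("invalid_input", "feature dimension mismatch")
  z <- sweep(sweep(x, 2L, basis$center), 2L, basis$scale, "/")
  z %*% basis$rotation
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d of %d components, %.1f%% variance retained\n",
              x$retained, length(x$explained),
              100 * sum(x$explained[seq_len(x$retained)])))
  invisible(x)
}
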