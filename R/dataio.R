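# Session containers and on-disk session format.
#
# All stored sample indices are 0-based; intervals are half-open [start, end).
# CSV files use comma separators with a decimal point and mandatory headers.
# EMG is stored channel-major as little-endian 32-bit floats next to a
# plain-text header sidecar.

#' Multichannel surface EMG recording
#'
#' @param samples numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz.
#' @param grid_shape integer vector `(rows, cols)` of the electrode grid;
#'   `prod(grid_shape)` must equal the number of channels.
#' @param bad_channel_mask logical per channel; `TRUE` marks an excluded
#'   (noisy) channel.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sample_rate, grid_shape,
                          bad_channel_mask = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop_mukin("invalid_configuration", "sample_rate must be positive")
  grid_shape <- as.integer(grid_shape)
  if (prod(grid_shape) != nrow(samples))
    stop_mukin("invalid_configuration",
               "number of channels must equal prod(grid_shape)")
  bad_channel_mask <- bad_channel_mask %||% rep(FALSE, nrow(samples))
  stopifnot(length(bad_channel_mask) == nrow(samples))
  structure(list(samples = samples, sample_rate = sample_rate,
                 grid_shape = grid_shape,
                 bad_channel_mask = as.logical(bad_channel_mask)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels (%dx%d grid), %d samples @ %g Hz, %d excluded\n",
              nrow(x$samples), x$grid_shape[1], x$grid_shape[2],
              ncol(x$samples), x$sample_rate, sum(x$bad_channel_mask)))
  invisible(x)
}

#' Set of motor unit spike trains
#'
#' @param units named list; each element a strictly increasing integer vector
#'   of 0-based discharge sample indices.
#' @param provenance one of `"ground_truth"`, `"corrupted"`, `"external"`.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(units, provenance = c("ground_truth", "corrupted",
                                                  "external")) {
  provenance <- match.arg(provenance)
  units <- lapply(units, function(u) as.integer(u))
  for (id in names(units)) {
    u <- units[[id]]
    if (length(u) && (any(u < 0L) || is.unsorted(u, strictly = TRUE)))
      stop_mukin("invalid_input", sprintf(
        "spike indices of unit %s must be nonnegative and strictly increasing", id))
  }
  if (is.null(names(units)) && length(units))
    names(units) <- sprintf("u%03d", seq_along(units))
  structure(list(units = units, provenance = provenance),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d units, %d discharges (%s)\n",
              length(x$units), sum(lengths(x$units)), x$provenance))
  invisible(x)
}

#' Wrist kinematics trace
#'
#' Per-sample joint angles in degrees for the three wrist degrees of freedom
#' (flexion/extension, pronation/supination, ulnar/radial deviation).
#'
#' @param angles numeric matrix with exactly 3 rows (DoF x samples), degrees.
#' @param sample_rate sampling rate in Hz.
#' @export
kinematics_trace <- function(angles, sample_rate) {
  angles <- as.matrix(angles)
  if (nrow(angles) != 3L)
    stop_mukin("corrupt_session", "kinematics must have exactly 3 DoF rows")
  if (!all(is.finite(angles)))
    stop_mukin("invalid_input", "kinematics must be finite")
  if (sample_rate <= 0)
    stop_mukin("invalid_configuration", "sample_rate must be positive")
  structure(list(angles = angles, sample_rate = sample_rate),
            class = "kinematics_trace")
}

#' Trial segmentation table
#'
#' One record per ramp episode: `trial_id`, `dof` (1..3), `direction` (+1/-1),
#' `start_sample`/`end_sample` (0-based, half-open), `ramp_duration_s`.
#'
#' @param records data.frame with the columns above.
#' @export
trial_segmentation <- function(records) {
  need <- c("trial_id", "dof", "direction", "start_sample", "end_sample",
            "ramp_duration_s")
  if (!all(need %in% names(records)))
    stop_mukin("invalid_input", "segmentation is missing required columns")
  if (any(records$end_sample <= records$start_sample))
    stop_mukin("invalid_input", "segmentation intervals must have end > start")
  o <- order(records$start_sample)
  r <- records[o, need]
  if (nrow(r) > 1L && any(r$start_sample[-1L] < r$end_sample[-nrow(r)]))
    stop_mukin("invalid_input", "ramp intervals must not overlap")
  rownames(r) <- NULL
  structure(r, class = c("trial_segmentation", "data.frame"))
}

#' Write a session to a directory
#'
#' Writes `emg.dat` (little-endian float32, channel-major) with `emg.hdr`
#' sidecar, `spikes.csv`, `kinematics.csv`, `segmentation.csv` and
#' `manifest.json` (seeds, config, config hash).
#'
#' @param session a session list as produced by [sim_session()] or
#'   [read_session()].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  emg <- session$emg
  n_ch <- nrow(emg$samples); n_s <- ncol(emg$samples)
  con <- file(file.path(path, "emg.dat"), "wb")
  on.exit(close(con), add = TRUE)
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.numeric(t(emg$samples)), con, size = 4L, endian = "little")
  hdr <- c(sprintf("n_channels: %d", n_ch),
           sprintf("n_samples: %d", n_s),
           sprintf("sample_rate: %.10g", emg$sample_rate),
           sprintf("grid_rows: %d", emg$grid_shape[1]),
           sprintf("grid_cols: %d", emg$grid_shape[2]),
           "dtype: float32", "byte_order: little", "order: channel-major",
           sprintf("bad_channels: %s",
                   paste(which(emg$bad_channel_mask) - 1L, collapse = " ")))
  writeLines(hdr, file.path(path, "emg.hdr"))

  sp <- session$spikes_dec %||% session$spikes
  spike_df <- data.frame(
    unit_id = rep(names(sp$units), lengths(sp$units)),
    sample_index = unlist(sp$units, use.names = FALSE) %||% integer(0))
  utils::write.csv(spike_df, file.path(path, "spikes.csv"), row.names = FALSE)

  kin <- session$kin
  kin_df <- data.frame(sample_index = seq_len(ncol(kin$angles)) - 1L,
                       dof1_deg = kin$angles[1, ], dof2_deg = kin$angles[2, ],
                       dof3_deg = kin$angles[3, ])
  utils::write.csv(kin_df, file.path(path, "kinematics.csv"), row.names = FALSE)

  seg_df <- as.data.frame(session$seg)
  utils::write.csv(seg_df, file.path(path, "segmentation.csv"),
                   row.names = FALSE)

  cfg <- session$config %||% list()
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    format = "mukin-session-1",
    seed = cfg$seed %||% NA,
    config = cfg,
    config_hash = unname(tools::md5sum(tf)),
    unit_ids = names(sp$units), # roster incl. silent units
    spike_provenance = sp$provenance,
    kinematics_sample_rate = kin$sample_rate,
    n_channels = n_ch, n_samples = n_s, sample_rate = emg$sample_rate)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_emg_header <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, ":\\s*")
  out <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = ":")),
                         vapply(kv, `[[`, "", 1L))
  out
}

#' Read a session from a directory
#'
#' Round-trips sessions written by [write_session()] losslessly for all
#' integer fields; EMG samples round-trip exactly at 32-bit float precision.
#'
#' @param path session directory.
#' @return list with elements `emg`, `spikes`, `kin`, `seg`, `config`, `id`.
#' @export
read_session <- function(path) {
  need <- c("emg.dat", "emg.hdr", "spikes.csv", "kinematics.csv",
            "segmentation.csv", "manifest.json")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss))
    stop_mukin("not_found", paste("missing session file(s):",
                                  paste(miss, collapse = ", ")))
  hdr <- read_emg_header(file.path(path, "emg.hdr"))
  n_ch <- as.integer(hdr$n_channels); n_s <- as.integer(hdr$n_samples)
  fs <- as.numeric(hdr$sample_rate)
  sz <- file.info(file.path(path, "emg.dat"))$size
  if (!identical(as.numeric(sz), 4 * as.numeric(n_ch) * n_s))
    stop_mukin("corrupt_session", "emg.dat size does not match header")
  con <- file(file.path(path, "emg.dat"), "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "numeric", n = n_ch * n_s, size = 4L, endian = "little")
  samples <- t(matrix(raw, nrow = n_s, ncol = n_ch))
  bad <- rep(FALSE, n_ch)
  if (nzchar(trimws(hdr$bad_channels %||% "")))
    bad[as.integer(strsplit(trimws(hdr$bad_channels), "\\s+")[[1]]) + 1L] <- TRUE
  emg <- emg_recording(samples, fs,
                       c(as.integer(hdr$grid_rows), as.integer(hdr$grid_cols)),
                       bad)

  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  spike_df <- utils::read.csv(file.path(path, "spikes.csv"))
  units <- lapply(split(spike_df$sample_index, spike_df$unit_id), sort)
  roster <- manifest$unit_ids %||% names(units)
  units <- stats::setNames(lapply(roster, function(id)
    as.integer(units[[id]] %||% integer(0))), roster)
  if (any(unlist(units, use.names = FALSE) >= n_s))
    stop_mukin("corrupt_session", "spike index beyond recording length")
  spikes <- spike_train_set(units,
                            manifest$spike_provenance %||% "external")

  kin_df <- utils::read.csv(file.path(path, "kinematics.csv"))
  if (!all(c("dof1_deg", "dof2_deg", "dof3_deg") %in% names(kin_df)))
    stop_mukin("corrupt_session", "kinematics must have 3 DoF columns")
  kin_rate <- manifest$kinematics_sample_rate %||% fs
  ang <- t(as.matrix(kin_df[, c("dof1_deg", "dof2_deg", "dof3_deg")]))
  dimnames(ang) <- NULL
  kin <- kinematics_trace(ang, kin_rate)
  if (kin_rate == fs && ncol(kin$angles) != n_s)
    stop_mukin("corrupt_session", "kinematics length does not match EMG")
  kin <- validate_alignment(emg, kin)$kin

  seg <- trial_segmentation(utils::read.csv(file.path(path,
                                                      "segmentation.csv")))
  list(emg = emg, spikes = spikes, spikes_dec = spikes, kin = kin, seg = seg,
       config = manifest$config,
       id = manifest$config_hash %||% basename(path))
}

#' Check and repair EMG/kinematics alignment
#'
#' Flags sample-rate and length mismatches; when rates differ, resamples the
#' kinematics to the EMG timebase by linear interpolation (feature windows are
#' defined on the EMG clock).
#'
#' @param emg an [emg_recording()].
#' @param kin a [kinematics_trace()].
#' @return list with `report` (character vector of findings, empty when
#'   aligned) and `kin` (the possibly resampled trace).
#' @export
validate_alignment <- function(emg, kin) {
  if (ncol(emg$samples) == 0L || ncol(kin$angles) == 0L)
    stop_mukin("invalid_input", "zero-length traces")
  report <- character(0)
  n <- ncol(emg$samples)
  if (kin$sample_rate != emg$sample_rate) {
    report <- c(report, sprintf("sample-rate mismatch: kin %g Hz vs EMG %g Hz; resampled",
                                kin$sample_rate, emg$sample_rate))
    t_kin <- (seq_len(ncol(kin$angles)) - 1L) / kin$sample_rate
    t_emg <- (seq_len(n) - 1L) / emg$sample_rate
    ang <- t(vapply(1:3, function(d)
      stats::approx(t_kin, kin$angles[d, ], xout = t_emg, rule = 2)$y,
      numeric(n)))
    kin <- kinematics_trace(ang, emg$sample_rate)
  } else if (ncol(kin$angles) != n) {
    report <- c(report, sprintf("length mismatch: kin %d vs EMG %d samples",
                                ncol(kin$angles), n))
  }
  list(report = report, kin = kin)
}
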