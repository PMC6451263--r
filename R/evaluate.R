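# Output smoothing, R^2 scoring, the repeated three-fold leave-one-ramp-out
# cross-validation plan, and the four-way feature-set comparison.

#' Median of three consecutive outputs
#'
#' Replaces each output by the median of itself and the two preceding
#' outputs (per DoF when given a matrix); the first two outputs use the
#' available prefix (median of one, then of two). Shift-equivariant and
#' monotone; removes isolated single-sample prediction spikes.
#'
#' @param x numeric vector or windows x DoF matrix.
#' @export
median3 <- function(x) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- median3(x[, j])
    return(out)
  }
  n <- length(x)
  if (n <= 1L) return(x)
  out <- numeric(n)
  out[1L] <- x[1L]
  out[2L] <- (x[1L] + x[2L]) / 2
  if (n >= 3L) {
    a <- x[1:(n - 2L)]; b <- x[2:(n - 1L)]; c <- x[3:n]
    out[3:n] <- a + b + c - pmax(a, b, c) - pmin(a, b, c)
  }
  out
}

#' Coefficient of determination per DoF
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the test-trace mean,
#' reported per DoF and averaged over DoFs; this metric normalizes for the
#' different ranges of motion of the individual DoFs. DoFs with zero-variance
#' truth are flagged `NA` and excluded from the mean.
#'
#' @param estimates windows x 3 matrix (or vector) of estimated angles.
#' @param truth matching matrix (or vector) of recorded angles.
#' @return list with `per_dof` and `mean`.
#' @export
r_squared <- function(estimates, truth) {
  estimates <- as.matrix(estimates); truth <- as.matrix(truth)
  if (!all(dim(estimates) == dim(truth)))
    stop_mukin("invalid_input", "estimates and truth must have equal shape")
  if (nrow(truth) < 2L) stop_mukin("invalid_input", "need >= 2 windows")
  per <- vapply(seq_len(ncol(truth)), function(d) {
    sst <- sum((truth[, d] - mean(truth[, d]))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((truth[, d] - estimates[, d])^2) / sst
  }, 0)
  list(per_dof = per, mean = mean(per, na.rm = TRUE))
}

#' Build a repeated three-fold leave-one-ramp-out cross-validation plan
#'
#' The design requires exactly three trials per DoF: in each fold one trial
#' of every DoF is held out for testing and the decoder is trained on the
#' remaining two; the three folds of a repeat test every trial exactly once.
#' Repeats differ by their random trial-to-fold assignment.
#'
#' @param seg a [trial_segmentation()].
#' @param repeats number of repeats (default 10).
#' @param seed integer seed.
#' @return object of class `cv_plan`: list with `repeats` and `folds`
#'   (`folds[[r]][[f]]` = character vector of held-out trial ids).
#' @export
make_cv_plan <- function(seg, repeats = 10L, seed = 1L) {
  s <- as.data.frame(seg)
  trials <- unique(s[, c("trial_id", "dof")])
  per_dof <- split(trials$trial_id, trials$dof)
  if (length(per_dof) != 3L || any(lengths(per_dof) != 3L))
    stop_mukin("unsupported_design",
               "the cross-validation design requires exactly 3 trials per DoF")
  set.seed(derive_seed(seed, "cvplan"))
  folds <- lapply(seq_len(repeats), function(r) {
    perm <- lapply(per_dof, sample)
    lapply(1:3, function(f) vapply(perm, `[[`, "", f))
  })
  structure(list(repeats = as.integer(repeats), folds = folds, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> 3 folds x %d repeats, one held-out ramp per DoF per fold\n",
              x$repeats))
  invisible(x)
}

#' Compare decoder feature sets under cross-validation
#'
#' For every repeat and fold of the plan, fits all stage parameters of each
#' requested feature set on the training ramps only, predicts the held-out
#' ramps (median-of-three smoothed) and scores them with per-DoF R^2.
#'
#' @param session an `mu_session` (single ramp speed).
#' @param kinds feature sets to compare (subset of TD, AM1, AM2, PROPOSED).
#' @param repeats cross-validation repeats (default 10).
#' @param seed seed for the fold assignments.
#' @param window a [window_spec()].
#' @param control a [decoder_control()] list.
#' @param verbose emit a progress message per fold.
#' @return object of class `mu_report`: a data.frame with one row per
#'   (kind, ramp_duration_s, repeat, fold, dof) cell and column `r2`.
#' @export
run_comparison <- function(session, kinds = decoder_kinds, repeats = 10L,
                           seed = 1L, window = window_spec(),
                           control = decoder_control(), verbose = FALSE) {
  kinds <- match.arg(kinds, decoder_kinds, several.ok = TRUE)
  session <- prepare_session(session, window)
  plan <- make_cv_plan(session$seg, repeats, seed)
  all_trials <- unique(session$prep$spans$trial_id)
  ramp <- session$config$ramp_duration %||% NA_real_
  cells <- list()
  for (r in seq_len(plan$repeats)) {
    for (f in 1:3) {
      test_trials <- plan$folds[[r]][[f]]
      train_trials <- setdiff(all_trials, test_trials)
      t0 <- proc.time()[3]
      decs <- fit_fold(session, train_trials, kinds, window, control)
      for (kind in kinds) {
        dec <- decs[[kind]]
        pred <- predict(dec, trials = test_trials, smooth = TRUE)
        rows <- attr(pred, "rows")
        r2 <- r_squared(pred, session$prep$targets[rows, , drop = FALSE])
        cells[[length(cells) + 1L]] <- data.frame(
          kind = kind, ramp_duration_s = ramp, rep = r, fold = f,
          dof = 1:3, r2 = r2$per_dof)
      }
      if (verbose)
        message(sprintf("repeat %d fold %d: %d kinds in %.1f s", r, f,
                        length(kinds), proc.time()[3] - t0))
    }
  }
  out <- do.call(rbind, cells)
  class(out) <- c("mu_report", "data.frame")
  out
}

#' Summarize a comparison report
#'
#' Mean and SD of R^2 over all (repeat, fold, DoF) cells, per feature set and
#' ramp duration.
#'
#' @param object an `mu_report`.
#' @param ... unused.
#' @export
summary.mu_report <- function(object, ...) {
  d <- as.data.frame(object)
  agg <- do.call(rbind, lapply(
    split(d, list(d$kind, d$ramp_duration_s), drop = TRUE), function(g)
      data.frame(kind = g$kind[1L], ramp_duration_s = g$ramp_duration_s[1L],
                 mean_r2 = mean(g$r2, na.rm = TRUE),
                 sd_r2 = stats::sd(g$r2, na.rm = TRUE),
                 n_cells = sum(!is.na(g$r2)))))
  rownames(agg) <- NULL
  agg[order(agg$ramp_duration_s, -agg$mean_r2), ]
}

#' @export
print.mu_report <- function(x, ...) {
  cat(sprintf("<mu_report> %d cells (%s)\n", nrow(x),
              paste(unique(x$kind), collapse = ", ")))
  print(summary(x))
  invisible(x)
}

#' Paired descriptive comparison of two feature sets
#'
#' Pairs R^2 cells by (ramp duration, repeat, fold, DoF), reports the mean
#' paired difference and a sign test (exact binomial on the sign of the
#' differences).
#'
#' @param report an `mu_report` containing both kinds.
#' @param kind_a,kind_b feature sets to compare (`kind_a - kind_b`).
#' @export
compare_kinds <- function(report, kind_a, kind_b) {
  d <- as.data.frame(report)
  key <- function(g) paste(g$ramp_duration_s, g$rep, g$fold, g$dof)
  a <- d[d$kind == kind_a, ]; b <- d[d$kind == kind_b, ]
  b <- b[match(key(a), key(b)), ]
  delta <- a$r2 - b$r2
  ok <- !is.na(delta) & delta != 0
  st <- if (any(ok))
    stats::binom.test(sum(delta[ok] > 0), sum(ok)) else NULL
  list(kind_a = kind_a, kind_b = kind_b, n = sum(!is.na(delta)),
       mean_delta = mean(delta, na.rm = TRUE),
       wins = sum(delta > 0, na.rm = TRUE),
       sign_test_p = if (is.null(st)) NA_real_ else st$p.value)
}

#' Boxplot of cross-validated R^2 by feature set
#' @param x an `mu_report`. @param ... passed to [graphics::boxplot()].
#' @export
plot.mu_report <- function(x, ...) {
  graphics::boxplot(r2 ~ kind, data = as.data.frame(x),
                    ylab = expression(R^2), xlab = "feature set", ...)
  invisible(x)
}
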