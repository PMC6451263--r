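# Model-based dimensionality reduction for motor unit populations.
#
# Physiological premise: motor neurons of a pool share a large fraction of
# their synaptic input (common drive), so every unit's discharge pattern is a
# noisy view of one underlying activation. Each unit's windowed spike count is
# mapped to a synaptic-input proxy (degrees) by a robustly fitted linear
# function; units are assigned to the DoF their counts correlate with most;
# and the per-DoF activation is the running median of the unit proxies
# together with the previous activation (which promotes smoothness and
# mitigates decomposition errors).

#' Assign motor units to degrees of freedom by correlation
#'
#' For each unit, the Pearson correlation between its windowed spike-count
#' series and each DoF's window-averaged angle is computed over the training
#' windows; the unit is assigned to the DoF with the highest absolute
#' correlation (the sign is retained). Units with zero-variance counts are
#' flagged unassignable.
#'
#' @param dsc windows x units spike-count matrix.
#' @param kin_windows windows x 3 matrix of window-averaged joint angles,
#'   degrees.
#' @return data.frame `unit_id`, `dof`, `correlation` (`NA` rows mark
#'   unassignable units).
#' @export
assign_dof <- function(dsc, kin_windows) {
  if (nrow(dsc) < 2L) stop_mukin("invalid_input", "need at least 2 windows")
  if (nrow(kin_windows) != nrow(dsc))
    stop_mukin("invalid_input", "kinematics not aligned to windows")
  ids <- colnames(dsc) %||% sprintf("u%03d", seq_len(ncol(dsc)))
  dof <- integer(ncol(dsc)); rho <- numeric(ncol(dsc))
  kin_sd <- apply(kin_windows, 2L, stats::sd)
  for (j in seq_len(ncol(dsc))) {
    v <- dsc[, j]
    if (stats::sd(v) == 0) { dof[j] <- NA_integer_; rho[j] <- NA_real_; next }
    r <- vapply(1:3, function(d)
      if (kin_sd[d] == 0) 0 else stats::cor(v, kin_windows[, d]), 0)
    dof[j] <- which.max(abs(r))
    rho[j] <- r[dof[j]]
  }
  data.frame(unit_id = ids, dof = dof, correlation = rho,
             stringsAsFactors = FALSE)
}

#' Robust linear map from spike counts to joint angle
#'
#' Fits `angle = slope * count + intercept` by iteratively reweighted least
#' squares with the Tukey bisquare weight function (tuning constant 4.685
#' times the robust scale, scale = MAD/0.6745 of the residuals), at most 50
#' iterations, relative parameter tolerance 1e-8.
#'
#' @param counts windowed spike counts (numeric vector).
#' @param angle assigned-DoF angle per window, degrees.
#' @param max_iter,tol,tuning IRLS controls.
#' @return object of class `g_function` with `slope`, `intercept`,
#'   `iterations`, `converged`.
#' @export
fit_g <- function(counts, angle, max_iter = 50L, tol = 1e-8,
                  tuning = 4.685) {
  if (length(counts) < 10L)
    stop_mukin("invalid_input", "need at least 10 windows")
  if (length(unique(counts)) < 2L)
    stop_mukin("degenerate_fit", "counts are constant")
  X <- cbind(1, counts)
  beta <- stats::lm.fit(X, angle)$coefficients
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    r <- angle - X %*% beta
    s <- stats::mad(r, center = 0) # median(|r|)/0.6745, residuals centred at 0
    if (s == 0) { converged <- TRUE; break }
    u <- r / (tuning * s)
    w <- as.vector(ifelse(abs(u) < 1, (1 - u^2)^2, 0))
    if (all(w == 0)) break
    fit <- stats::lm.wfit(X, angle, w)
    beta_new <- fit$coefficients
    if (any(is.na(beta_new))) break
    if (max(abs(beta_new - beta)) <=
        tol * max(1, max(abs(beta)))) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
    if (it >= max_iter) break
  }
  structure(list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
                 iterations = it, converged = converged),
            class = "g_function")
}

#' @export
print.g_function <- function(x, ...) {
  cat(sprintf("<g_function> angle = %.4g * count + %.4g (%d iterations%s)\n",
              x$slope, x$intercept, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Evaluate a unit's synaptic-input proxy series
#'
#' @param g a [fit_g()] result.
#' @param counts spike counts per window.
#' @return numeric vector of proxies (degrees), one per window.
#' @export
estimate_alpha <- function(g, counts) {
  g$slope * counts + g$intercept
}

#' Recursive median combination of unit proxies
#'
#' Per window `r`, the pool activation is
#' `a_r = median(alpha_1r, ..., alpha_nr, a_{r-1})`, evaluated sequentially
#' with `a_0 = a0`; an even-cardinality median is the mean of the two central
#' order statistics. The previous-activation term promotes smoothness; the
#' median makes the estimate robust to decomposition errors in up to
#' `floor((n-1)/2)` units.
#'
#' @param alphas windows x units matrix of proxies (degrees).
#' @param a0 initialization (degrees, default 0: neutral wrist).
#' @return numeric activation series, one value per window.
#' @export
combine_median <- function(alphas, a0 = 0) {
  alphas <- as.matrix(alphas)
  if (ncol(alphas) == 0L) stop_mukin("empty_pool", "no units in pool")
  out <- numeric(nrow(alphas))
  prev <- a0
  for (r in seq_len(nrow(alphas))) {
    prev <- stats::median(c(alphas[r, ], prev))
    out[r] <- prev
  }
  out
}

#' Per-DoF pool activations from spike counts
#'
#' Groups units by their assigned DoF (dropping unassignable units and units
#' whose assignment correlation magnitude is below `min_cor`), evaluates each
#' unit's proxy series through its fitted linear map and combines each pool
#' with the recursive median. DoFs with empty pools emit the constant `a0`
#' and are flagged.
#'
#' @param dsc windows x units spike-count matrix.
#' @param assignment data.frame from [assign_dof()].
#' @param g_list named list of [fit_g()] results per unit id.
#' @param a0 initialization per DoF (recycled).
#' @param min_cor minimum absolute assignment correlation (default 0.2).
#' @return windows x 3 activation matrix with attribute `"empty_pools"`
#'   (logical per DoF).
#' @export
compute_activations <- function(dsc, assignment, g_list, a0 = 0,
                                min_cor = 0.2) {
  a0 <- rep(a0, length.out = 3L)
  W <- nrow(dsc)
  act <- matrix(0, W, 3L, dimnames = list(NULL, paste0("a", 1:3)))
  empty <- logical(3L)
  keep <- !is.na(assignment$dof) & abs(assignment$correlation) >= min_cor &
    assignment$unit_id %in% names(g_list)
  for (d in 1:3) {
    ids <- assignment$unit_id[keep & assignment$dof == d]
    if (!length(ids)) {
      act[, d] <- a0[d]; empty[d] <- TRUE
      next
    }
    alphas <- vapply(ids, function(id)
      estimate_alpha(g_list[[id]], dsc[, id]), numeric(W))
    act[, d] <- combine_median(matrix(alphas, nrow = W), a0[d])
  }
  if (all(empty)) stop_mukin("empty_model", "all pools are empty")
  if (any(empty))
    warning(sprintf("empty pool(s) for DoF %s; emitting constant a0",
                    paste(which(empty), collapse = ", ")))
  attr(act, "empty_pools") <- empty
  act
}

#' Proposed neural feature matrix
#'
#' Columns are the three per-DoF activations followed by the PCA-reduced
#' residual-EMG TD features; this is the proposed feature set for the final
#' linear regression.
#'
#' @param activations windows x 3 activation matrix.
#' @param residual_td_pca windows x k PCA-projected residual TD features.
#' @export
neural_feature_matrix <- function(activations, residual_td_pca) {
  if (nrow(activations) != nrow(residual_td_pca))
    stop_mukin("invalid_input", "misaligned windows")
  k <- ncol(residual_td_pca)
  out <- cbind(activations, residual_td_pca)
  colnames(out) <- c(paste0("a", 1:3),
                     if (k) paste0("res_pc", seq_len(k)))
  out
}
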