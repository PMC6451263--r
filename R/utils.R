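# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a session seed and a component tag
#'
#' All stochastic components draw their seed from one session seed through this
#' map, so that a single integer reproduces an entire session bit-identically
#' while components remain decoupled (changing one component's draws does not
#' shift another's).
#'
#' @param seed integer master seed.
#' @param tag character tag naming the component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 69069 + h * 7919) %% 2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_mukin <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "mukin_error")))
}

#' Scatter-add a waveform at a set of sample positions
#'
#' Places `w` starting at each 0-based `starts0` and sums overlaps. Placements
#' that do not fit fully inside `[0, n)` are skipped (edge discharges carry no
#' signal, matching the spike-triggered-averaging support rule).
#' @keywords internal
overlay_waveform <- function(starts0, w, n) {
  L <- length(w)
  out <- numeric(n)
  starts0 <- starts0[starts0 >= 0 & (starts0 + L) <= n]
  ns <- length(starts0)
  if (ns == 0L) return(out)
  idx <- rep(starts0, each = L) + seq_len(L) # 1-based
  acc <- rowsum(rep(w, times = ns), idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Scatter-add a multichannel template (channels x L) at sample positions
#' @return list(cols = touched 1-based sample indices, block = C x length(cols))
#' @keywords internal
overlay_template_matrix <- function(starts0, tmpl, n) {
  L <- ncol(tmpl)
  starts0 <- starts0[starts0 >= 0 & (starts0 + L) <= n]
  ns <- length(starts0)
  if (ns == 0L) return(list(cols = integer(0), block = NULL))
  idx <- rep(starts0, each = L) + seq_len(L)
  x <- t(tmpl)[rep(seq_len(L), times = ns), , drop = FALSE] # (L*ns) x C
  acc <- rowsum(x, idx)
  list(cols = as.integer(rownames(acc)), block = t(acc))
}

# Half-open 0-based interval membership for sample indices.
in_spans <- function(idx0, spans) {
  if (nrow(spans) == 0L) return(rep(FALSE, length(idx0)))
  hit <- rep(FALSE, length(idx0))
  for (k in seq_len(nrow(spans))) {
    hit <- hit | (idx0 >= spans$start[k] & idx0 < spans$end[k])
  }
  hit
}

span_mask <- function(spans, n) {
  m <- logical(n)
  for (k in seq_len(nrow(spans))) {
    a <- max(0L, spans$start[k])
    b <- min(n, spans$end[k])
    if (b > a) m[(a + 1L):b] <- TRUE
  }
  m
}
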