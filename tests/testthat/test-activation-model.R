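test_that("units are assigned to the DoF their counts track, sign retained", {
  set.seed(21)
  ang <- cbind(sin(seq(0, 6 * pi, length.out = 120)) * 50,
               cos(seq(0, 5 * pi, length.out = 120)) * 40,
               sin(seq(0, 3 * pi, length.out = 120)) * 30)
  dsc <- cbind(u1 = ang[, 1] / 5 + 12,
               u2 = -ang[, 2] / 4 + 15,
               u3 = rep(3, 120))
  a <- assign_dof(dsc, ang)
  expect_equal(a$dof[1], 1L)
  expect_equal(a$correlation[1], 1, tolerance = 1e-9)
  expect_equal(a$dof[2], 2L)
  expect_equal(a$correlation[2], -1, tolerance = 1e-9)
  expect_true(is.na(a$dof[3])) # zero-variance counts are unassignable

  # argmax over explicit correlations
  x <- rnorm(120)
  y <- cbind(x + rnorm(120, 0, 0.2), rnorm(120), rnorm(120))
  a2 <- assign_dof(cbind(u = x + 10), y)
  expect_equal(a2$dof, 1L)
})

test_that("robust bisquare regression recovers linear maps and resists outliers", {
  # noiseless recovery
  counts <- rep(0:9, 5)
  g <- fit_g(counts, 3 * counts + 1)
  expect_equal(g$slope, 3, tolerance = 1e-8)
  expect_equal(g$intercept, 1, tolerance = 1e-8)
  expect_true(g$converged)

  # with 10% gross outliers the bisquare fit beats OLS
  set.seed(22)
  wins <- 0L
  for (i in 1:40) {
    x <- rpois(200, 6)
    y <- 2.5 * x - 4 + rnorm(200, 0, 2)
    out <- sample(200, 20)
    y[out] <- 500
    gb <- fit_g(x, y)
    ols <- stats::lm.fit(cbind(1, x), y)$coefficients
    err_b <- abs(gb$slope - 2.5) + abs(gb$intercept + 4)
    err_o <- abs(ols[2] - 2.5) + abs(ols[1] + 4)
    if (err_b < err_o) wins <- wins + 1L
  }
  expect_gte(wins, 38L)

  expect_error(fit_g(rep(2, 50), rnorm(50)), class = "mukin_error")
  expect_error(fit_g(1:5, 1:5), class = "mukin_error")
})

test_that("bisquare fit agrees with the reference IRLS implementation", {
  skip_if_not_installed("MASS")
  set.seed(23)
  for (i in 1:5) {
    x <- rpois(150, 5)
    y <- 1.7 * x + 3 + rnorm(150, 0, 3)
    y[sample(150, 10)] <- y[sample(150, 10)] + 80
    g <- fit_g(x, y)
    ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
    expect_equal(g$slope, unname(coef(ref)[2]), tolerance = 0.05)
    expect_equal(g$intercept, unname(coef(ref)[1]), tolerance = 0.5)
  }
})

test_that("alpha series evaluate the fitted linear map per window", {
  g <- structure(list(slope = 3, intercept = 1), class = "g_function")
  expect_equal(estimate_alpha(g, 2), 7)
  g0 <- structure(list(slope = 0, intercept = 5), class = "g_function")
  expect_equal(estimate_alpha(g0, c(1, 9, 4)), rep(5, 3))
  expect_length(estimate_alpha(g, rpois(37, 2)), 37)
})

test_that("recursive median combination follows the order-statistics rules", {
  # constant proxies lock in from the second window
  a <- combine_median(matrix(4, 10, 3), a0 = 0)
  expect_equal(a[1], 4) # median(4,4,4,0) = 4 at n = 3
  expect_equal(a[2:10], rep(4, 9))

  # hand-enumerated medians
  expect_equal(combine_median(matrix(c(2, 3, 10), 1), a0 = 3), 3)
  expect_equal(combine_median(matrix(5, 1, 1), a0 = 1), 3) # mean of (1,5)

  expect_error(combine_median(matrix(0, 5, 0)), class = "mukin_error")
})

test_that("median combination is bounded, monotone, idempotent and robust", {
  # exhaustive enumeration for n <= 4 over a value grid
  grid <- c(-1, 0, 1, 2)
  for (n in 1:4) {
    combos <- as.matrix(expand.grid(rep(list(grid), n)))
    for (a0 in c(-1, 0, 2)) {
      for (r in seq_len(nrow(combos))) {
        vals <- combos[r, ]
        a1 <- combine_median(matrix(vals, 1), a0)
        lo <- min(vals, a0); hi <- max(vals, a0)
        expect_gte(a1, lo); expect_lte(a1, hi)
        # monotonicity: raising one proxy never lowers the activation
        for (j in seq_len(n)) {
          up <- vals; up[j] <- up[j] + 1
          expect_gte(combine_median(matrix(up, 1), a0), a1)
        }
      }
    }
  }

  # idempotence: identical series equal the activation from r = 2 onward
  x <- rnorm(20)
  am <- combine_median(matrix(rep(x, 4), 20), a0 = 0)
  expect_equal(am[2:20], x[2:20])

  # randomized checks at larger pool sizes
  set.seed(24)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    W <- 8
    alphas <- matrix(rnorm(W * n, 0, 20), W)
    a <- combine_median(alphas, 0)
    for (r in 1:W) {
      prev <- if (r == 1) 0 else a[r - 1]
      expect_gte(a[r], min(alphas[r, ], prev))
      expect_lte(a[r], max(alphas[r, ], prev))
    }
    # corrupting floor((n-1)/2) proxies keeps the activation within the
    # clean-value spread
    k <- (n - 1) %/% 2
    bad <- alphas
    bad[3, seq_len(k)] <- 1e6
    ab <- combine_median(bad, 0)
    clean_vals <- c(alphas[3, (k + 1):n], ab[2])
    expect_lte(ab[3], max(clean_vals))
    expect_gte(ab[3], min(clean_vals))
  }

  # smoothness: the recursion term never increases the step size
  vals_grid <- c(-2, 0, 1, 3)
  for (n in 1:3) {
    combos <- as.matrix(expand.grid(rep(list(vals_grid), n)))
    for (prev in vals_grid) {
      for (r in seq_len(nrow(combos))) {
        with_prev <- stats::median(c(combos[r, ], prev))
        without <- stats::median(combos[r, ])
        expect_lte(abs(with_prev - prev), abs(without - prev) + 1e-12)
      }
    }
  }
})

test_that("pool activations compose exact inverse maps and resist one outlier", {
  # counts exactly linear in the angle: activations reproduce the angle
  set.seed(25)
  W <- 60
  ang <- cbind(60 * sin(seq(0, 4 * pi, length.out = W)),
               60 * cos(seq(0, 2 * pi, length.out = W)),
               30 * sin(seq(0, 6 * pi, length.out = W)))
  dsc <- NULL; ids <- character(0)
  for (d in 1:3) for (j in 1:3) {
    ids <- c(ids, sprintf("d%du%d", d, j))
    dsc <- cbind(dsc, ang[, d] * j / 10 + 20)
  }
  colnames(dsc) <- ids
  assignment <- assign_dof(dsc, ang)
  g_list <- lapply(seq_along(ids), function(k)
    fit_g(dsc[, k], ang[, assignment$dof[k]]))
  names(g_list) <- ids
  act <- compute_activations(dsc, assignment, g_list)
  expect_equal(unclass(act)[, ], ang[, ], tolerance = 1e-6,
               ignore_attr = TRUE)

  # one wildly corrupted proxy leaves a 9-unit pool's median unchanged
  dsc10 <- dsc[, 1:3]
  for (j in 4:10) dsc10 <- cbind(dsc10, ang[, 1] * j / 12 + 15)
  colnames(dsc10) <- sprintf("u%02d", 1:10)
  asg <- assign_dof(dsc10, ang)
  gl <- lapply(1:10, function(k) fit_g(dsc10[, k], ang[, 1]))
  names(gl) <- colnames(dsc10)
  act_clean <- suppressWarnings(compute_activations(dsc10, asg, gl))[, 1]
  gl_bad <- gl
  gl_bad[["u10"]]$intercept <- 1000
  gl_bad[["u10"]]$slope <- 0
  act_bad <- suppressWarnings(
    compute_activations(dsc10, asg, gl_bad))[, 1]
  expect_equal(act_bad, act_clean, tolerance = 1e-9)

  # empty pool emits constant a0 with a warning
  expect_warning(
    act2 <- compute_activations(dsc10, asg, gl, a0 = c(0, 2, 0)),
    "empty pool")
  expect_true(all(act2[, 2] == 2))
  expect_true(attr(act2, "empty_pools")[2])
})

test_that("the proposed feature matrix concatenates activations and residual PCs", {
  act <- matrix(rnorm(40 * 3), 40)
  res <- matrix(rnorm(40 * 20), 40)
  f <- neural_feature_matrix(act, res)
  expect_equal(ncol(f), 23L)
  expect_equal(colnames(f)[1:3], c("a1", "a2", "a3"))
  expect_error(neural_feature_matrix(act, res[1:30, ]),
               class = "mukin_error")
})
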