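# Single-time-point lag-conditioned machinery: summaries, per-group and
# combined regressions, the contrast, and the full test against the
# explicit-matrix oracle.

test_that("group_lag_summary matches textbook sums and flags degeneracy", {
  s <- group_lag_summary(c(-2, 0, 2), c(-1, 0, 1), group = 0, j = 2)
  expect_equal(s$rho, 1)
  expect_equal(s$mean_curr, 0)
  expect_equal(s$sd_curr, 2)
  expect_true(s$rho_defined)

  s2 <- group_lag_summary(c(5, 5, 5, 5), c(1, 2, 3, 4))
  expect_identical(s2$sd_curr, 0)
  expect_false(s2$rho_defined)
  expect_true(is.na(s2$rho))

  expect_error(group_lag_summary(1:3, 1:4), "equal length")
  expect_error(group_lag_summary(1, 1), "at least 2")

  set.seed(101)
  for (i in 1:25) {
    x <- rnorm(6, sd = runif(1, 0.5, 3))
    y <- 0.7 * x + rnorm(6)
    s <- group_lag_summary(y, x)
    o <- oracle_moments(x, y)
    expect_equal(s$rho, o$r, tolerance = 1e-12)
    expect_equal(s$mean_curr, o$mean_y, tolerance = 1e-12)
    expect_equal(s$sd_curr, o$sd_y, tolerance = 1e-12)
    expect_equal(s$sd_prev, o$sd_x, tolerance = 1e-12)
  }
})

test_that("fit_group_regression: exact fits, identities, errors", {
  f <- fit_group_regression(c(-2, 0, 2), c(-1, 0, 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$mse, 0)
  expect_equal(f$se_conditional_mean, 0)

  f2 <- fit_group_regression(1:4, 1:4)
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 0)
  expect_equal(f2$mse, 0)

  expect_error(fit_group_regression(1:2, 1:2), "at least 3")
  expect_error(fit_group_regression(c(1, 2, 3), c(2, 2, 2)),
               "constant within group")

  # MSE = S_yy (1 - rho^2) / (n - 2); fitted value at the lagged mean
  # is the current-time sample mean, exactly
  set.seed(202)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    x <- rnorm(n)
    y <- 1 + 0.6 * x + rnorm(n, sd = 0.5)
    f <- fit_group_regression(y, x)
    s <- group_lag_summary(y, x)
    syy <- sum((y - mean(y))^2)
    expect_equal(f$mse, syy * (1 - s$rho^2) / (n - 2), tolerance = 1e-10)
    expect_equal(f$fitted_at_mean, mean(y), tolerance = 1e-12)
    expect_equal(f$slope, s$rho * s$sd_curr / s$sd_prev, tolerance = 1e-12)
    # direct residual computation agrees
    res <- y - (f$intercept + f$slope * x)
    expect_equal(f$mse, sum(res^2) / (n - 2), tolerance = 1e-12)
  }
})

test_that("fit_combined_regression: exact two-line fit, symmetry, oracle", {
  cf <- fit_combined_regression(c(-2, 0, 2, 1, 3, 5),
                                c(-1, 0, 1, -1, 0, 1),
                                c(0, 0, 0, 1, 1, 1))
  expect_equal(cf$beta, c(0, 3, 2, 0), tolerance = 1e-12)
  expect_equal(cf$sse, 0, tolerance = 1e-20)

  # identical data in both groups: no group effect, no interaction
  set.seed(303)
  x <- rnorm(5)
  y <- 1 + x + rnorm(5, sd = 0.3)
  cfs <- fit_combined_regression(c(y, y), c(x, x), rep(c(0, 1), each = 5))
  expect_equal(cfs$beta[2], 0, tolerance = 1e-10)
  expect_equal(cfs$beta[4], 0, tolerance = 1e-10)

  expect_error(fit_combined_regression(rnorm(4), rnorm(4), c(0, 0, 1, 1)),
               "n >= 5")
  expect_error(fit_combined_regression(rnorm(6), rep(1, 6),
                                       rep(c(0, 1), each = 3)),
               "constant within group")
  expect_error(fit_combined_regression(rnorm(6), rnorm(6), rep(0, 6)),
               "both groups")

  # brute-force matrix oracle + per-group SSE decomposition
  set.seed(304)
  for (i in 1:50) {
    n0 <- sample(3:6, 1); n1 <- sample(3:6, 1)
    g <- rep(c(0L, 1L), c(n0, n1))
    prev <- rnorm(n0 + n1)
    curr <- 0.5 + g + 0.8 * prev + 0.3 * g * prev + rnorm(n0 + n1)
    cf <- fit_combined_regression(curr, prev, g)
    o <- oracle_homologous(curr, prev, g)
    expect_equal(cf$beta, o$beta, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(cf$sse, o$sse, tolerance = 1e-10)
    expect_equal(cf$xtx_inv, o$xtx_inv, tolerance = 1e-8,
                 ignore_attr = TRUE)
    f0 <- fit_group_regression(curr[g == 0], prev[g == 0])
    f1 <- fit_group_regression(curr[g == 1], prev[g == 1])
    expect_equal(cf$sse, f0$sse + f1$sse, tolerance = 1e-10)
    # covariance symmetric PSD
    expect_equal(cf$beta_cov, t(cf$beta_cov), tolerance = 1e-12)
    expect_true(all(eigen(cf$beta_cov, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("homologous_contrast: mean-difference and variance identities", {
  # exact two-line example: d_hat = 3 - 0
  curr <- c(-2, 0, 2, 1, 3, 5); prev <- c(-1, 0, 1, -1, 0, 1)
  g <- c(0, 0, 0, 1, 1, 1)
  cf <- fit_combined_regression(curr, prev, g)
  s0 <- group_lag_summary(curr[1:3], prev[1:3], 0)
  s1 <- group_lag_summary(curr[4:6], prev[4:6], 1)
  ct <- homologous_contrast(cf, s0, s1)
  expect_equal(ct$d_hat, 3, tolerance = 1e-12)

  set.seed(405)
  for (i in 1:50) {
    n0 <- sample(3:6, 1); n1 <- sample(3:6, 1)
    g <- rep(c(0L, 1L), c(n0, n1))
    prev <- rnorm(n0 + n1, mean = 3)
    curr <- g + prev + rnorm(n0 + n1, sd = 0.7)
    cf <- fit_combined_regression(curr, prev, g)
    s0 <- group_lag_summary(curr[g == 0], prev[g == 0], 0)
    s1 <- group_lag_summary(curr[g == 1], prev[g == 1], 1)
    ct <- homologous_contrast(cf, s0, s1)
    # point estimate is the plain difference of current-time means
    expect_equal(ct$d_hat, mean(curr[g == 1]) - mean(curr[g == 0]),
                 tolerance = 1e-10)
    # leverage-at-the-mean identity: z (X'X)^-1 z' = 1/n0 + 1/n1
    lev <- drop(ct$contrast %*% cf$xtx_inv %*% ct$contrast)
    expect_equal(lev, 1 / n0 + 1 / n1, tolerance = 1e-10)
    expect_equal(ct$se_d^2, cf$mse * (1 / n0 + 1 / n1), tolerance = 1e-10)
  }
})

test_that("homologous_test matches the explicit-matrix oracle on all fields", {
  set.seed(506)
  for (i in 1:60) {
    n0 <- sample(3:6, 1); n1 <- sample(3:6, 1)  # n <= 12
    ds <- random_dataset(n0 = n0, n1 = n1, m = 4)
    j <- sample(2:4, 1)
    ht <- homologous_test(ds, j)
    o <- oracle_homologous(ds$volumes[, j], ds$volumes[, j - 1], ds$group)
    expect_equal(ht$d_hat, o$d_hat, tolerance = 1e-10)
    expect_equal(ht$se_d, o$se_d, tolerance = 1e-10)
    expect_equal(ht$t_stat, o$t_stat, tolerance = 1e-10)
    expect_identical(ht$df, as.integer(o$df))
    expect_equal(ht$p_two_sided, o$p_two_sided, tolerance = 1e-10)
    expect_equal(ht$p_one_sided_greater, o$p_one_sided_greater,
                 tolerance = 1e-10)
    expect_equal(ht$p_one_sided_less, o$p_one_sided_less,
                 tolerance = 1e-10)
    expect_equal(ht$contrast, o$contrast, tolerance = 1e-12)
    expect_equal(ht$regression$beta, o$beta, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("homologous_test edge cases and errors", {
  ds <- random_dataset()
  expect_error(homologous_test(ds, 1), "baseline")
  expect_error(homologous_test(ds, 99), "exceeds")

  # identical groups: t = 0, two-sided p = 1
  set.seed(607)
  x <- rnorm(4); y <- 2 + x + rnorm(4, sd = 0.4)
  ds_same <- growth_dataset(rbind(cbind(x, y), cbind(x, y)),
                            group = rep(c(0L, 1L), each = 4),
                            times = c(1, 2))
  ht <- homologous_test(ds_same, 2)
  expect_equal(ht$t_stat, 0, tolerance = 1e-10)
  expect_equal(ht$p_two_sided, 1, tolerance = 1e-10)

  # groups of size < 3 rejected
  ds_small <- growth_dataset(matrix(rnorm(10), 5),
                             group = c(0, 0, 0, 1, 1), times = 1:2)
  expect_error(homologous_test(ds_small, 2), "at least 3 animals")

  # constant lagged values: hard error suggesting the t test
  vol <- cbind(rep(2, 6), rnorm(6))
  ds_const <- growth_dataset(vol, rep(c(0L, 1L), each = 3), 1:2)
  expect_error(homologous_test(ds_const, 2), "t test")
})
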