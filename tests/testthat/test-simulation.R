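test_that("study1_config validates", {
  expect_error(study1_config(sigma = 0), "positive")
  expect_error(study1_config(1, beta = 1:3), "length 4")
  expect_error(study1_config(1, n_total = 7), "even")
  expect_error(study1_config(1, n_total = 4), "even")
  expect_error(study1_config(1, reps = 0), ">= 1")
  cfg <- study1_config(0.4, seed = 5)
  expect_s3_class(cfg, "study1_config")
  expect_true(cfg$calibrate)
  expect_identical(cfg$sides, "greater")
})

test_that("simulate_study1 is reproducible and controls size under the null", {
  a <- simulate_study1(study1_config(0.7, reps = 300, seed = 42))
  b <- simulate_study1(study1_config(0.7, reps = 300, seed = 42))
  expect_identical(a$homologous$rejections, b$homologous$rejections)
  expect_identical(a$ttest$rejections, b$ttest$rejections)

  # beta1 = 0 null: both tests within 3 MC SEs of alpha, two-sided,
  # 10,000 replicates (the nonzero beta2 makes the lag informative but
  # the homologous null true)
  nul <- simulate_study1(study1_config(sigma = 0.7, beta = c(0, 0, 1, 0.5),
                                       reps = 10000, sides = "two",
                                       seed = 43))
  tol <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(nul$homologous$power - 0.05), tol)
  expect_lt(abs(nul$ttest$power - 0.05), tol)
})

test_that("simulate_study1 tracks the closed-form conditional power", {
  cfg <- study1_config(sigma = 0.6, beta = c(0, 0.8, 1, 0), reps = 20000,
                       seed = 44)
  sim <- simulate_study1(cfg)
  an <- analytic_homologous_power(5, 5, 0.8, 0.6, sides = "greater")
  expect_lt(abs(sim$homologous$power - an),
            3 * sqrt(an * (1 - an) / 20000))
})

test_that("make_cs_covariance: values, eigenvalues, range checks", {
  expect_equal(make_cs_covariance(2, 1, 0.5),
               matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(make_cs_covariance(3, 2, 0), 2 * diag(3))
  # eigenvalues: var + (m-1) cov once, var - cov with multiplicity m-1
  v <- make_cs_covariance(6, 1, 0.5)
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev), 1 + 5 * 0.5, tolerance = 1e-12)
  expect_equal(min(ev), 0.5, tolerance = 1e-12)
  expect_equal(sort(ev)[1:5], rep(0.5, 5), tolerance = 1e-12)
  expect_error(make_cs_covariance(4, 1, 1), "positive definiteness")
  expect_error(make_cs_covariance(4, 1, -0.5), "positive definiteness")
  expect_error(make_cs_covariance(4, -1, 0), "positive")
})

test_that("scenario builders produce the stated worlds", {
  s <- scenario_overlap_null()
  expect_equal(s$means, matrix(0, 2, 6))
  expect_identical(s$n_per_group, 16L)
  expect_equal(s$cov, make_cs_covariance(6, 1, 0.5))

  lin <- scenario_linear_divergence(final_diff = 1)
  expect_equal(lin$means[2, 6] - lin$means[1, 6], 1)
  expect_equal(lin$means[2, 1], 0)

  late <- scenario_late_divergence(final_diff = 2)
  expect_equal(late$means[2, ], c(rep(0, 5), 2))

  nn <- scenario_nonlinear_null()
  expect_equal(nn$means[2, 1], 0, tolerance = 1e-12)
  expect_equal(nn$means[2, 6], 0, tolerance = 1e-12)
  expect_gt(max(nn$means[2, ]), 0.9)

  expect_error(study2_scenario(matrix(0, 3, 4)), "2 x m")
  expect_error(study2_scenario(matrix(0, 2, 3), cov = diag(c(1, -1, 1))),
               "positive definite")
})

test_that("study-2 panel draws have the specified CS covariance", {
  set.seed(55)
  s <- scenario_overlap_null(m = 4, n_per_group = 8)
  ch <- chol(s$cov)
  draws <- do.call(rbind, replicate(600, homotest:::draw_study2_panel(s, ch),
                                    simplify = FALSE))
  emp <- cov(draws)  # 9600 panel rows
  expect_lt(max(abs(emp - s$cov)), 0.06)
  # Frobenius distance shrinks with more replicates
  emp_small <- cov(draws[1:400, ])
  d_small <- sqrt(sum((emp_small - s$cov)^2))
  d_big <- sqrt(sum((emp - s$cov)^2))
  expect_lt(d_big, d_small)
})

test_that("simulate_study2: reproducibility and location invariance", {
  s <- scenario_overlap_null(n_per_group = 8)
  a <- simulate_study2(s, reps = 200, seed = 7, include_lmm = FALSE)
  b <- simulate_study2(s, reps = 200, seed = 7, include_lmm = FALSE)
  expect_identical(a$homologous$rejections, b$homologous$rejections)
  expect_identical(a$ttest$rejections, b$ttest$rejections)

  # shifting both groups' trajectories by the same constant changes
  # nothing under a shared seed
  shifted <- study2_scenario(s$means + 7, n_per_group = 8, cov = s$cov)
  d <- simulate_study2(shifted, reps = 200, seed = 7, include_lmm = FALSE)
  expect_identical(a$homologous$rejections, d$homologous$rejections)
  expect_identical(a$ttest$rejections, d$ttest$rejections)
})

test_that("simulate_study2 runs the mixed model and tracks analytic t power", {
  # small-scale smoke + power sanity on a linear divergence scenario
  s <- scenario_linear_divergence(n_per_group = 16, final_diff = 1)
  sim <- simulate_study2(s, reps = 400, seed = 8)
  expect_named(sim, c("homologous", "ttest", "lmm"))
  expect_identical(sim$lmm$n_failed, 0L)
  an <- analytic_t_power(16, 1, 1, sides = "two")
  expect_lt(abs(sim$ttest$power - an), 3 * sqrt(an * (1 - an) / 400))
  # informative lag: the homologous test should not be less powerful
  expect_gt(sim$homologous$power, sim$ttest$power - 0.05)
})
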