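#' Monte-Carlo power estimate
#'
#' @param test_name Label of the procedure.
#' @param rejections Number of rejecting replicates.
#' @param reps Number of replicates in the denominator.
#' @param config Arbitrary configuration echo, stored as-is.
#' @param n_failed Replicates dropped (e.g. mixed-model failures).
#' @return An object of class `power_estimate`: list with `test`,
#'   `rejections`, `reps`, `power`, `mc_se` (binomial
#'   `sqrt(p (1 - p) / reps)`), `n_failed`, `config`.
#' @export
power_estimate <- function(test_name, rejections, reps, config = list(),
                           n_failed = 0L) {
  stopifnot(reps >= 1, rejections >= 0, rejections <= reps)
  p <- rejections / reps
  structure(
    list(test = test_name, rejections = as.integer(rejections),
         reps = as.integer(reps), power = p,
         mc_se = sqrt(p * (1 - p) / reps),
         n_failed = as.integer(n_failed), config = config),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("%s: power = %.4f (MC SE %.4f; %d/%d rejections%s)\n",
              x$test, x$power, x$mc_se, x$rejections, x$reps,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Configuration for the single-time-point regression power study
#'
#' Describes one cell of the regression-model simulation: lagged values
#' are standard normal, outcomes follow the four-parameter interaction
#' model `Y = b0 + b1 x + b2 y_lag + b3 x y_lag + e` with
#' `e ~ N(0, sigma^2)`, and the homologous and pooled t tests are
#' applied to every replicate.
#'
#' `calibrate = TRUE` centers each group's simulated lagged values at
#' zero within every replicate *for the homologous test only*. Centering
#' pins both groups' conditional adjustment terms to zero — holding the
#' two adjustments equal, so the homologous null differs from the
#' alternative exactly by the treatment effect `b1` and the test's power
#' equals the closed-form noncentral-t value
#' ([analytic_homologous_power()] with `conditional_sd = sigma`). The
#' t test is the standard cross-sectional procedure and always sees the
#' marginal (uncentered) outcomes, whose SD is
#' `sqrt(b2^2 + sigma^2)` for standard-normal lagged values (plus the
#' `b3` contribution in group 1); calibration is a device internal to
#' the homologous framework, not a change to the experiment. Both tests
#' share the same error draws within a replicate. With
#' `calibrate = FALSE` the homologous test, too, runs on the uncentered
#' data, in which the two groups' realized adjustment terms differ by a
#' random amount.
#'
#' @param sigma Error SD (> 0).
#' @param beta Length-4 coefficient vector `(b0, b1, b2, b3)`; `b0` is
#'   conventionally 0.
#' @param n_total Total animals, split equally (even, >= 6).
#' @param reps Monte-Carlo replications (>= 1).
#' @param alpha Significance level.
#' @param sides Sidedness applied to both tests.
#' @param seed Optional integer seed.
#' @param calibrate Center lagged values within group (default `TRUE`).
#' @return An object of class `study1_config`.
#' @export
study1_config <- function(sigma, beta = c(0, 1, 1, 0), n_total = 10,
                          reps = 10000, alpha = 0.05,
                          sides = c("greater", "two", "less"),
                          seed = NULL, calibrate = TRUE) {
  sides <- match.arg(sides)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (length(beta) != 4) stop("'beta' must have length 4", call. = FALSE)
  if (n_total %% 2 != 0 || n_total < 6) {
    stop("'n_total' must be even and >= 6", call. = FALSE)
  }
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  structure(
    list(sigma = sigma, beta = as.numeric(beta),
         n_total = as.integer(n_total), reps = as.integer(reps),
         alpha = alpha, sides = sides, seed = seed,
         calibrate = isTRUE(calibrate)),
    class = "study1_config"
  )
}

#' Regression-model power study: homologous versus pooled t test
#'
#' Per replicate: draw lagged values from N(0, 1) for each group
#' (optionally centering them within group, see [study1_config()]),
#' generate outcomes from the interaction model, then apply the
#' homologous test (df n - 4) and the pooled two-sample t test
#' (df n - 2) to the same data. Both tests see identical replicates, so
#' their powers are directly comparable.
#'
#' @param config A [study1_config()].
#' @return List with elements `homologous` and `ttest`, each a
#'   [power_estimate()].
#' @examples
#' simulate_study1(study1_config(sigma = 0.4, reps = 200, seed = 1))
#' @export
simulate_study1 <- function(config) {
  stopifnot(inherits(config, "study1_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_total
  ng <- n %/% 2L
  x <- rep(c(0L, 1L), each = ng)
  b <- config$beta
  rej_hom <- 0L
  rej_t <- 0L
  for (r in seq_len(config$reps)) {
    ylag <- stats::rnorm(n)
    eps <- stats::rnorm(n, sd = config$sigma)
    # marginal outcomes: what the cross-sectional t test sees
    y_marg <- b[1] + b[2] * x + b[3] * ylag + b[4] * x * ylag + eps
    if (config$calibrate) {
      # calibrated lagged values (zero group means) for the homologous
      # framework, reusing the same error draws
      ylag_h <- ylag
      ylag_h[1:ng] <- ylag_h[1:ng] - mean(ylag_h[1:ng])
      ylag_h[(ng + 1):n] <- ylag_h[(ng + 1):n] - mean(ylag_h[(ng + 1):n])
      y_h <- b[1] + b[2] * x + b[3] * ylag_h + b[4] * x * ylag_h + eps
    } else {
      ylag_h <- ylag
      y_h <- y_marg
    }
    core <- hom_core(y_h, ylag_h, x)
    p_hom <- pick_p(t_pvalues(core$t_stat, core$df), config$sides)
    if (p_hom <= config$alpha) rej_hom <- rej_hom + 1L
    tt <- two_sample_t(y_marg[1:ng], y_marg[(ng + 1):n],
                       sides = config$sides, alpha = config$alpha)
    if (tt$reject) rej_t <- rej_t + 1L
  }
  list(
    homologous = power_estimate("homologous", rej_hom, config$reps,
                                config = unclass(config)),
    ttest = power_estimate("t test", rej_t, config$reps,
                           config = unclass(config))
  )
}

#' Compound-symmetry covariance matrix
#'
#' Constant variance on the diagonal and constant covariance
#' off-diagonal. Positive definite iff
#' `-variance / (m - 1) < covariance < variance` (eigenvalues are
#' `variance + (m - 1) covariance`, once, and `variance - covariance`,
#' m - 1 times).
#'
#' @param m Dimension (>= 1).
#' @param variance Diagonal value (> 0).
#' @param covariance Off-diagonal value.
#' @return An `m x m` matrix.
#' @examples
#' make_cs_covariance(6, 1, 0.5)
#' @export
make_cs_covariance <- function(m, variance = 1, covariance = 0.5) {
  if (variance <= 0) stop("'variance' must be positive", call. = FALSE)
  if (m > 1 && (covariance <= -variance / (m - 1) || covariance >= variance)) {
    stop("'covariance' must lie in (-variance/(m-1), variance) for ",
         "positive definiteness", call. = FALSE)
  }
  v <- matrix(covariance, m, m)
  diag(v) <- variance
  v
}

#' Longitudinal panel scenario for the comparative power study
#'
#' A scenario is a pair of expected-outcome trajectories (one per
#' group), a per-group sample size and an error covariance across the
#' time points. Animals are sampled as trajectory + correlated
#' multivariate-normal error.
#'
#' @param means 2 x m numeric matrix: row 1 is group 0's expected
#'   outcome at each time point, row 2 group 1's.
#' @param n_per_group Animals per group.
#' @param cov m x m positive-definite error covariance; defaults to
#'   compound symmetry with unit variance and covariance 0.5.
#' @return An object of class `study2_scenario`.
#' @export
study2_scenario <- function(means, n_per_group = 16,
                            cov = make_cs_covariance(ncol(means), 1, 0.5)) {
  means <- as.matrix(means)
  if (nrow(means) != 2 || ncol(means) < 2) {
    stop("'means' must be a 2 x m matrix with m >= 2", call. = FALSE)
  }
  if (!isTRUE(all.equal(cov, t(cov))) ||
      any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("'cov' must be symmetric positive definite", call. = FALSE)
  }
  if (ncol(cov) != ncol(means)) {
    stop("'cov' dimension must match the number of time points",
         call. = FALSE)
  }
  dimnames(means) <- NULL
  structure(
    list(means = means, n_per_group = as.integer(n_per_group), cov = cov),
    class = "study2_scenario"
  )
}

#' Null scenario: the two groups' trajectories coincide
#'
#' Both groups have expected outcome zero at every time point; errors
#' are compound-symmetric with unit variance and covariance 0.5. All
#' rejection rates estimate type-I error.
#'
#' @param m Number of time points.
#' @param n_per_group Animals per group.
#' @return A [study2_scenario()].
#' @export
scenario_overlap_null <- function(m = 6, n_per_group = 16) {
  study2_scenario(matrix(0, nrow = 2, ncol = m), n_per_group = n_per_group)
}

#' Reconstructed non-null / non-linear scenario builders
#'
#' Qualitative reconstructions of the remaining comparative-study
#' scenario shapes (the original trajectories are shown only
#' graphically and are not tabulated): a transient bump that returns to
#' overlap at the final time point (null at the end, non-linear, where
#' a linear mixed model's extrapolated contrast misbehaves), a linear
#' divergence, and a late divergence concentrated in the last interval.
#' These are synthetic stand-ins intended for qualitative comparisons,
#' not numeric reproduction.
#'
#' @param m Number of time points.
#' @param n_per_group Animals per group.
#' @param bump Peak group-1 elevation of the transient bump.
#' @param final_diff Group difference at the final time point.
#' @return A [study2_scenario()].
#' @name scenario_builders
NULL

#' @rdname scenario_builders
#' @export
scenario_nonlinear_null <- function(m = 6, n_per_group = 16, bump = 1) {
  mu1 <- bump * sin(pi * (seq_len(m) - 1) / (m - 1))  # 0 at both ends
  study2_scenario(rbind(rep(0, m), mu1), n_per_group = n_per_group)
}

#' @rdname scenario_builders
#' @export
scenario_linear_divergence <- function(m = 6, n_per_group = 16,
                                       final_diff = 1) {
  mu1 <- final_diff * (seq_len(m) - 1) / (m - 1)
  study2_scenario(rbind(rep(0, m), mu1), n_per_group = n_per_group)
}

#' @rdname scenario_builders
#' @export
scenario_late_divergence <- function(m = 6, n_per_group = 16,
                                     final_diff = 1) {
  mu1 <- c(rep(0, m - 1), final_diff)
  study2_scenario(rbind(rep(0, m), mu1), n_per_group = n_per_group)
}

# Draw one replicate's panels: (2 * n_per_group) x m outcome matrix,
# group-0 rows first. chol_cov is the upper-triangular Cholesky factor.
draw_study2_panel <- function(scenario, chol_cov) {
  n <- scenario$n_per_group
  m <- ncol(scenario$means)
  err <- matrix(stats::rnorm(2 * n * m), nrow = 2 * n) %*% chol_cov
  mu <- scenario$means[rep(1:2, each = n), , drop = FALSE]
  mu + err
}

#' Comparative power study on longitudinal panels
#'
#' Per replicate: draw each animal's full time series as the scenario
#' trajectory plus correlated error, then apply three procedures to the
#' same data — (a) the homologous test at the final time point,
#' conditioning on the penultimate one; (b) the pooled two-sample t
#' test at the final time point; (c) the linear mixed model with
#' group-by-time interaction and random intercepts, testing the group
#' contrast at the final time. All tests are two-sided.
#'
#' The mixed model is fitted once and refitted to each replicate's
#' response (identical design throughout), which keeps 10,000-replicate
#' runs tractable. Replicates where the mixed model fails to fit are
#' counted in `n_failed` and excluded from its denominator only.
#'
#' @param scenario A [study2_scenario()].
#' @param reps Monte-Carlo replications.
#' @param alpha Significance level.
#' @param seed Optional integer seed.
#' @param include_lmm Fit the mixed model (default `TRUE`); disable for
#'   quick homologous/t-only runs.
#' @param lmm_df_method Passed to the mixed-model contrast; `"normal"`
#'   (Wald z) by default.
#' @return List with elements `homologous`, `ttest` and (if requested)
#'   `lmm`, each a [power_estimate()].
#' @examples
#' simulate_study2(scenario_overlap_null(), reps = 50, seed = 1,
#'                 include_lmm = FALSE)
#' @export
simulate_study2 <- function(scenario, reps = 10000, alpha = 0.05,
                            seed = NULL, include_lmm = TRUE,
                            lmm_df_method = c("normal", "residual")) {
  stopifnot(inherits(scenario, "study2_scenario"))
  lmm_df_method <- match.arg(lmm_df_method)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_per_group
  m <- ncol(scenario$means)
  group <- rep(c(0L, 1L), each = n)
  chol_cov <- chol(scenario$cov)
  t_final <- m

  template <- NULL
  long_skel <- NULL
  if (include_lmm) {
    long_skel <- data.frame(
      animal_id = factor(rep(seq_len(2 * n), each = m)),
      group = rep(group, each = m),
      time = rep(seq_len(m), times = 2 * n)
    )
  }

  rej_hom <- 0L
  rej_t <- 0L
  rej_lmm <- 0L
  lmm_failed <- 0L
  for (r in seq_len(reps)) {
    y <- draw_study2_panel(scenario, chol_cov)
    core <- hom_core(y[, m], y[, m - 1], group)
    if (t_pvalues(core$t_stat, core$df)$p_two_sided <= alpha) {
      rej_hom <- rej_hom + 1L
    }
    tt <- two_sample_t(y[group == 0L, m], y[group == 1L, m],
                       sides = "two", alpha = alpha)
    if (tt$reject) rej_t <- rej_t + 1L
    if (include_lmm) {
      resp <- as.vector(t(y))  # animal-major, matching long_skel
      res <- if (is.null(template)) {
        long_skel$volume <- resp
        tryCatch(suppressMessages(lme4::lmer(
          volume ~ group + time + group:time + (1 | animal_id),
          data = long_skel, REML = TRUE)),
          error = function(e) NULL)
      } else {
        tryCatch(
          suppressWarnings(suppressMessages(
            lme4::refit(template, newresp = resp))),
          error = function(e) NULL)
      }
      if (!is.null(res) && is.null(template)) template <- res
      if (is.null(res)) {
        lmm_failed <- lmm_failed + 1L
      } else {
        ct <- lmm_contrast_at(res, t_final = t_final,
                              df_method = lmm_df_method, alpha = alpha)
        if (isTRUE(ct$reject)) rej_lmm <- rej_lmm + 1L
      }
    }
  }

  cfg <- list(scenario = unclass(scenario), reps = reps, alpha = alpha,
              seed = seed)
  out <- list(
    homologous = power_estimate("homologous", rej_hom, reps, config = cfg),
    ttest = power_estimate("t test", rej_t, reps, config = cfg)
  )
  if (include_lmm) {
    out$lmm <- power_estimate("LMM", rej_lmm, reps - lmm_failed,
                              config = cfg, n_failed = lmm_failed)
  }
  out
}
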