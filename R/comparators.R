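#' Pooled-variance two-sample t test
#'
#' The standard cross-sectional comparator: Student's t with the pooled
#' variance estimate on n0 + n1 - 2 degrees of freedom. The difference is
#' oriented as group 1 minus group 0, so `sides = "greater"` tests
#' whether group 1 exceeds group 0.
#'
#' @param y0 Numeric vector of group-0 outcomes.
#' @param y1 Numeric vector of group-1 outcomes.
#' @param sides `"two"`, `"greater"` or `"less"`.
#' @param alpha Significance level for the rejection flag.
#' @return An object of class `t_test_result`: list with `diff`, `se`,
#'   `t_stat`, `df`, the three p-values, `p_value`, `reject`, `sides`,
#'   `alpha`, `n0`, `n1`.
#' @examples
#' two_sample_t(rnorm(5), rnorm(5, 1))
#' @export
two_sample_t <- function(y0, y1, sides = c("two", "greater", "less"),
                         alpha = 0.05) {
  sides <- match.arg(sides)
  n0 <- length(y0)
  n1 <- length(y1)
  if (n0 < 2 || n1 < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  diff <- mean(y1) - mean(y0)
  df <- n0 + n1 - 2L
  sp2 <- ((n0 - 1) * stats::var(y0) + (n1 - 1) * stats::var(y1)) / df
  if (sp2 == 0) {
    if (diff != 0) {
      stop("zero pooled variance with a nonzero mean difference: ",
           "the t statistic is undefined", call. = FALSE)
    }
    se <- 0
    t_stat <- 0
  } else {
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    t_stat <- diff / se
  }
  p <- t_pvalues(t_stat, df)
  structure(
    list(diff = diff, se = se, t_stat = t_stat, df = df,
         p_two_sided = p$p_two_sided,
         p_one_sided_greater = p$p_one_sided_greater,
         p_one_sided_less = p$p_one_sided_less,
         p_value = pick_p(p, sides),
         reject = pick_p(p, sides) <= alpha,
         sides = sides, alpha = alpha, n0 = n0, n1 = n1),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat("Pooled two-sample t test\n")
  cat(sprintf("  diff = %.4g, SE = %.4g, t = %.4g on %d df, p (%s) = %.4g\n",
              x$diff, x$se, x$t_stat, x$df, x$sides, x$p_value))
  invisible(x)
}

# Noncentral-t rejection probability for a t statistic with the given
# df, noncentrality and sidedness at level alpha.
nct_power <- function(df, ncp, alpha, sides) {
  switch(sides,
         two = {
           crit <- stats::qt(1 - alpha / 2, df)
           stats::pt(-crit, df, ncp) + stats::pt(crit, df, ncp,
                                                 lower.tail = FALSE)
         },
         greater = stats::pt(stats::qt(1 - alpha, df), df, ncp,
                             lower.tail = FALSE),
         less = stats::pt(stats::qt(alpha, df), df, ncp))
}

#' Exact power of the pooled two-sample t test
#'
#' Noncentral-t tail probability with noncentrality
#' `delta / (sd * sqrt(2 / n))` and 2n - 2 degrees of freedom, for a
#' balanced design with `n` per group.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param delta True mean difference (group 1 - group 0).
#' @param sd Common outcome standard deviation (> 0).
#' @param alpha Significance level in (0, 1).
#' @param sides `"two"`, `"greater"` or `"less"`.
#' @return The rejection probability.
#' @examples
#' analytic_t_power(16, delta = 1, sd = 1)  # ~0.78
#' @export
analytic_t_power <- function(n_per_group, delta, sd, alpha = 0.05,
                             sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  if (n_per_group < 2) stop("'n_per_group' must be >= 2", call. = FALSE)
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  nct_power(df = 2 * n_per_group - 2,
            ncp = delta / (sd * sqrt(2 / n_per_group)),
            alpha = alpha, sides = sides)
}

#' Exact power of the homologous (lag-conditioned) test
#'
#' Closed-form oracle for designs in which, conditional on the lagged
#' values, the contrast variance is `conditional_sd^2 * (1/n0 + 1/n1)`
#' (exactly so when each group's lagged values are centered, since the
#' contrast leverage equals 1/n0 + 1/n1 identically). The reference
#' distribution is noncentral t on n0 + n1 - 4 degrees of freedom.
#'
#' @param n0,n1 Group sizes (n0 + n1 >= 5).
#' @param delta True conditional mean difference.
#' @param conditional_sd Residual SD of the conditional model (> 0); the
#'   marginal SD times `sqrt(1 - rho^2)`.
#' @param alpha Significance level in (0, 1).
#' @param sides `"two"`, `"greater"` or `"less"`.
#' @return The rejection probability.
#' @examples
#' analytic_homologous_power(5, 5, delta = 1, conditional_sd = 0.4,
#'                           sides = "greater")
#' @export
analytic_homologous_power <- function(n0, n1, delta, conditional_sd,
                                      alpha = 0.05,
                                      sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  if (n0 + n1 < 5) stop("n0 + n1 must be >= 5", call. = FALSE)
  if (conditional_sd <= 0) {
    stop("'conditional_sd' must be positive", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  }
  nct_power(df = n0 + n1 - 4,
            ncp = delta / (conditional_sd * sqrt(1 / n0 + 1 / n1)),
            alpha = alpha, sides = sides)
}

#' Linear mixed model contrast at the final time point
#'
#' The longitudinal comparator: fixed effects for group, time
#' (continuous) and their interaction, with a per-animal random
#' intercept, fitted by REML via \pkg{lme4}. The reported estimate is
#' the Wald contrast `group + t_final * group:time`, i.e. the fitted
#' group difference at the last measurement time.
#'
#' @param long_data Data frame with columns `animal_id`, `group` (0/1),
#'   `time` (numeric), `volume`; complete panels.
#' @param df_method `"normal"` (Wald z, default) or `"residual"`
#'   (t on n_obs - 4 df). The large-sample normal reference is standard
#'   for Wald tests from random-intercept fits.
#' @param reml Fit by REML (default) or ML.
#' @param alpha Significance level for the rejection flag.
#' @return An object of class `lmm_result`: list with `estimate`, `se`,
#'   `stat`, `p_two_sided`, `reject`, `converged`, `t_final`,
#'   `df_method`, and the `fit` (a `merMod`).
#' @export
lmm_group_diff_at_final <- function(long_data,
                                    df_method = c("normal", "residual"),
                                    reml = TRUE, alpha = 0.05) {
  df_method <- match.arg(df_method)
  req <- c("animal_id", "group", "time", "volume")
  if (!all(req %in% names(long_data))) {
    stop("'long_data' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(long_data$time)) < 2) {
    stop("at least 2 time points are required", call. = FALSE)
  }
  for (g in 0:1) {
    if (length(unique(long_data$animal_id[long_data$group == g])) < 2) {
      stop("at least 2 animals per group are required", call. = FALSE)
    }
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      volume ~ group + time + group:time + (1 | animal_id),
      data = long_data, REML = reml)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(estimate = NA_real_, se = NA_real_,
                          stat = NA_real_, p_two_sided = NA_real_,
                          reject = NA, converged = FALSE,
                          t_final = max(long_data$time),
                          df_method = df_method, fit = NULL),
                     class = "lmm_result"))
  }
  lmm_contrast_at(fit, t_final = max(long_data$time),
                  df_method = df_method, alpha = alpha)
}

# Wald contrast group + t_final * group:time from a fitted merMod.
lmm_contrast_at <- function(fit, t_final, df_method, alpha) {
  fe <- lme4::fixef(fit)
  L <- c(0, 1, 0, t_final)[match(names(fe),
                                 c("(Intercept)", "group", "time",
                                   "group:time"))]
  est <- sum(L * fe)
  se <- sqrt(drop(t(L) %*% as.matrix(stats::vcov(fit)) %*% L))
  stat <- est / se
  conv <- is.null(fit@optinfo$conv$lme4$code) ||
    all(fit@optinfo$conv$lme4$code >= 0)
  p <- if (df_method == "normal") {
    2 * stats::pnorm(-abs(stat))
  } else {
    2 * stats::pt(-abs(stat), df = stats::nobs(fit) - 4)
  }
  structure(
    list(estimate = est, se = se, stat = stat, p_two_sided = p,
         reject = p <= alpha, converged = conv, t_final = t_final,
         df_method = df_method, fit = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model group contrast at the final time point\n")
  if (!x$converged) cat("  (fit did not converge)\n")
  cat(sprintf("  estimate = %.4g, SE = %.4g, stat = %.4g (%s), p = %.4g\n",
              x$estimate, x$se, x$stat, x$df_method, x$p_two_sided))
  invisible(x)
}
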