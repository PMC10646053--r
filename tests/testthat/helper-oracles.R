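# Brute-force oracles, independent of the package's QR/streamlined paths:
# explicit design matrix, explicit normal-equations solve, textbook sums.

# Full explicit-matrix implementation of the lag-conditioned test:
# X = [1, x, y_lag, x*y_lag], beta = (X'X)^-1 X'Y, contrast
# z = (0, 1, m1p - m0p, m1p), t on n - 4 df.
oracle_homologous <- function(curr, prev, group) {
  X <- cbind(1, group, prev, group * prev)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% curr
  resid <- curr - X %*% beta
  sse <- sum(resid^2)
  n <- length(curr)
  df <- n - 4
  mse <- sse / df
  m0p <- mean(prev[group == 0])
  m1p <- mean(prev[group == 1])
  z <- c(0, 1, m1p - m0p, m1p)
  d_hat <- drop(t(z) %*% beta)
  se_d <- sqrt(mse * drop(t(z) %*% xtx_inv %*% z))
  t_stat <- d_hat / se_d
  p_greater <- pt(t_stat, df, lower.tail = FALSE)
  p_less <- pt(t_stat, df)
  list(beta = drop(beta), beta_cov = mse * xtx_inv, xtx_inv = xtx_inv,
       sse = sse, mse = mse, df = df, contrast = z,
       d_hat = d_hat, se_d = se_d, t_stat = t_stat,
       p_two_sided = min(1, 2 * min(p_greater, p_less)),
       p_one_sided_greater = p_greater, p_one_sided_less = p_less)
}

# Textbook sum-based moments: means, SDs, Pearson r from raw sums.
oracle_moments <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r_num <- n * sxy - sx * sy
  r_den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  list(mean_x = sx / n, mean_y = sy / n,
       sd_x = sqrt((sxx - sx^2 / n) / (n - 1)),
       sd_y = sqrt((syy - sy^2 / n) / (n - 1)),
       r = r_num / r_den)
}

# Pooled two-sample t from first principles.
oracle_pooled_t <- function(y0, y1) {
  n0 <- length(y0); n1 <- length(y1)
  sp2 <- (sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)) / (n0 + n1 - 2)
  diff <- mean(y1) - mean(y0)
  t_stat <- diff / sqrt(sp2 * (1 / n0 + 1 / n1))
  list(diff = diff, t_stat = t_stat, df = n0 + n1 - 2L,
       p_two = 2 * pt(-abs(t_stat), n0 + n1 - 2))
}

# Random paired-volume dataset with controllable lag correlation.
random_dataset <- function(n0 = 4, n1 = 4, m = 3, rho = 0.8, sd = 1,
                           trend = 2) {
  n <- n0 + n1
  vol <- matrix(NA_real_, n, m)
  vol[, 1] <- rnorm(n, mean = 5, sd = sd)
  for (j in 2:m) {
    vol[, j] <- trend + rho * vol[, j - 1] +
      rnorm(n, sd = sd * sqrt(1 - rho^2))
  }
  growth_dataset(vol, group = rep(c(0L, 1L), c(n0, n1)),
                 times = seq_len(m))
}

# Semianalytic size of the lag-conditioned test under a *marginal* null
# (equal group means, lag correlation rho, equal group sizes): the
# estimand D = slope * (difference of realized lag means, centered) is
# random with sd rho*sigma*sqrt(2/n); against the conditional SE this
# yields a noncentrality ~ N(0, rho^2/(1-rho^2)) and a rejection rate
# above alpha. Integrates the noncentral-t tail over that distribution.
oracle_marginal_null_size <- function(n_per_group, rho, alpha = 0.05) {
  df <- 2 * n_per_group - 4
  crit <- qt(1 - alpha / 2, df)
  sd_ncp <- rho / sqrt(1 - rho^2)
  integrate(function(u) {
    (pt(-crit, df, u) + pt(crit, df, u, lower.tail = FALSE)) *
      dnorm(u, 0, sd_ncp)
  }, -Inf, Inf)$value
}

# GLS fixed effects under a block compound-symmetry marginal covariance
# (random-intercept model): beta = (X'V^-1 X)^-1 X'V^-1 y.
oracle_gls_fixef <- function(long_data, sigma2_b, sigma2_e) {
  ids <- unique(long_data$animal_id)
  X <- cbind(1, long_data$group, long_data$time,
             long_data$group * long_data$time)
  V <- matrix(0, nrow(X), nrow(X))
  for (id in ids) {
    idx <- which(long_data$animal_id == id)
    V[idx, idx] <- sigma2_b
  }
  diag(V) <- diag(V) + sigma2_e
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% long_data$volume))
}
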