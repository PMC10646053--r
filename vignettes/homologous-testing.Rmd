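---
title: "Lag-conditioned testing of tumor growth curves: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lag-conditioned testing of tumor growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homotest)
```

# The model

Let $Y_{x_i,ij}$ be the tumor volume of animal $i$ in arm $x_i \in
\{0,1\}$ at time point $j$, with $n_0$ and $n_1$ animals per arm and
$n = n_0 + n_1$. The cross-sectional null at time $j$ is
$E(Y_{0,j}) = E(Y_{1,j})$, conventionally tested with a two-sample $t$
test. The homologous null conditions each arm on its own realized lagged
group mean:

$$H_0:\; E(Y_{0,j} \mid Y_{0,j-1} = \bar y_{0,j-1})
      = E(Y_{1,j} \mid Y_{1,j-1} = \bar y_{1,j-1}).$$

Assuming a linear conditional mean within each arm, both sides are
embedded in one interaction regression at time $j$,

$$Y = \beta_0 + \beta_1 x + \beta_2\, y_{j-1} + \beta_3\, x\, y_{j-1}
      + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_j^2)\ \text{iid},$$

which fits each arm's simple regression line independently (the combined
SSE equals the sum of the two per-arm SSEs — a tested identity). The
group difference of conditional means is the contrast
$z = (0,\, 1,\, \bar y_{1,j-1} - \bar y_{0,j-1},\, \bar y_{1,j-1})$
applied to $\hat\beta$. Two algebraic identities drive everything:

1. **The point estimate never changes.** $z\hat\beta =
   \bar y_{1,j} - \bar y_{0,j}$ exactly, because a fitted simple
   regression evaluated at the covariate mean equals the outcome mean.
2. **The leverage collapses.** $z (X'X)^{-1} z' = 1/n_0 + 1/n_1$
   exactly, for the same reason.

Hence the statistic is the familiar difference of means divided by
$\sqrt{\mathrm{MSE}\,(1/n_0 + 1/n_1)}$, where MSE is the pooled residual
mean square on $n - 4$ degrees of freedom, referred to $t_{n-4}$.
Because $\mathrm{Var}(Y_j \mid Y_{j-1}) = \mathrm{Var}(Y_j)(1-\rho^2)$,
the expected SE shrinks by $\sqrt{1-\rho^2}$ relative to the pooled
$t$ test — the entire efficiency gain, bought for two degrees of
freedom. Per-arm conditional SEs reported alongside are
$\sqrt{\mathrm{MSE}_g / n_g}$ with $\mathrm{MSE}_g$ on $n_g - 2$ df
(equal to $S_{yy}(1-\hat\rho^2)/(n_g-2)$, another tested identity).
One source formula prints the arm-1 conditional variance with an $n_0$
denominator; we treat that as a typographical slip and use $n_1$, which
is the symmetric least-squares result.

# Which null you are testing — and the price

The conditional and marginal nulls coincide only asymptotically. In a
finite experiment the homologous estimand is

$$D = \beta_1 + \beta_2(\bar y_{1,j-1} - \bar y_{0,j-1})
      + \beta_3 \bar y_{1,j-1},$$

which retains the *realized* lag-mean difference. Under equal marginal
means with common lag slope $\rho$, $D = \rho\,\Delta\bar y_{j-1}$ is a
mean-zero random variable, not zero. The $t$ statistic then has a random
noncentrality distributed $N(0,\ \rho^2/(1-\rho^2))$ for equal arms, and
the two-sided rejection rate of the cross-sectional null exceeds
$\alpha$: semianalytic integration (implemented as an independent oracle
in the test suite) gives 0.087 at $\rho = 0.5$, $n = 16$/arm, and 0.33
at $\rho = 0.9$, $n = 5$/arm, both confirmed by Monte Carlo in the
suite. Two practical consequences:

* A homologous rejection means "given where each arm was yesterday,
  today's means differ" — a sharper but different question than "the
  arms differ on average". If strict marginal type-I control is the
  requirement, use the $t$ test.
* Published size claims for this procedure under marginal nulls are not
  reproducible from the statistic as defined; the discrepancy is
  documented in this package's acceptance suite, where the affected
  assertion is deliberately left failing with the semianalytic value
  asserted alongside (see `tests/testthat/test-acceptance.R`). No
  centering or calibration of the lagged values can remove the effect:
  both the estimate and its SE are invariant to within-arm location
  shifts of the lag (identities 1–2 above).

# Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `sides` | all tests | `"two"` (tests), `"greater"` (regression power study) | Two-sided is the reporting convention; the regression power study's reference values are reproduced only by one-sided $\alpha=0.05$, so its engine defaults to that. |
| `alpha` | all tests | 0.05 | Field convention. |
| minimum group size | `homologous_test` | 3/arm, $n \ge 5$ | $\mathrm{MSE}_g$ needs $n_g - 2 \ge 1$; the combined fit needs $n - 4 \ge 1$. |
| `log_transform` | loaders | off | The test applies to volumes as provided; log-scale analysis is a load-time flag, matching practice of analyzing raw or log volumes. |
| missing values | loaders | rejected | Complete cases only; pairwise deletion would make the $n-4$ bookkeeping ambiguous. |
| multiplicity | report | none | Per-time-point p-values are reported unadjusted, matching field practice; noted in the report docs. |

Degenerate designs are hard errors, never silent fallbacks: a constant
lagged value within an arm (singular design) raises an error suggesting
the plain $t$ test; zero pooled variance with a nonzero difference is an
error; zero-variance lag correlations are flagged `NA`, not set to 0.
The first time point has no lag, so the report emits the $t$ test there
and marks the homologous columns not applicable.

# The Monte-Carlo engines

**Regression-model study** (`simulate_study1`). Lagged values are
standard normal, $n = 10$ split equally; outcomes follow the interaction
model with $\beta_0 = 0$; both tests see 10,000 replicates. The
reference results are reproduced with one-sided $\alpha = 0.05$ despite
the accompanying text saying two-sided — the printed 0.05-size rows and
headline powers match one-sided noncentral-$t$ values, so the engine
defaults to one-sided and the discrepancy is recorded rather than
resolved. The *calibration* (`calibrate = TRUE`) centers each arm's
lagged values at zero within every replicate, pinning both conditional
adjustment terms to zero so that the homologous power equals the
closed-form `analytic_homologous_power()` value exactly. Centering is
applied to the homologous test's data only: the $t$ test is the standard
cross-sectional procedure and sees the marginal outcomes (SD
$\sqrt{\beta_2^2 + \sigma^2}$ for standard-normal lags), sharing the
same error draws. Applying the $t$ test to the centered data instead
would shrink its power well below every reference value (the pooled
variance still includes the $\beta_2^2$ component while the mean
difference no longer does) — verified against the closed forms during
development.

**Longitudinal panel study** (`simulate_study2`). Each animal's
$m$-vector is a scenario trajectory plus multivariate-normal error with
compound-symmetry covariance (variance 1, covariance 0.5; eigenvalues
$1+(m-1)\cdot 0.5$ and $0.5$). Three procedures run on identical
replicates: the homologous test at the final time point (two-sided), the
pooled $t$ test there, and an lme4 random-intercept model with
group + time + group×time fixed effects (time continuous, $1..m$),
Wald-$z$ contrast `group + m * group:time`, REML. The mixed model is
fitted once and `refit()` to each replicate's response, which keeps
10,000-replicate runs to a few minutes on one CPU; failures are counted
and excluded from its denominator only. Only the fully-overlapping null
scenario is pinned by published values; the other trajectory shapes
exist only as a figure, so the shipped builders (`scenario_nonlinear_null`,
`scenario_linear_divergence`, `scenario_late_divergence`) are labeled
reconstructions used for qualitative claims (the extrapolating LMM
contrast inflates type-I error under non-linear trends; the
per-time-point tests do not extrapolate).

A single seeded RNG stream drives each simulation run, with every
procedure consuming the same replicate data; runs are bit-reproducible
from the seed.

# The synthetic-data generator

`generate_fixture()` emulates a small xenograft experiment: 4 animals
per arm measured on days 3, 5, 7, 12, 14, 17, 19, 21, 24, volumes
rising from ~4 to ~200–250 mm³, adjacent-day correlations around 0.9.
Mechanism: each arm has a linear log-volume mean curve; each animal
deviates from it by a stationary AR(1) process (lag correlation `rho`,
stationary SD `noise_sd`, defaults 0.9 and 0.25 chosen to match the
correlation range and ~25% coefficient of variation typical of such
studies); volumes are the exponentials. On the log scale the generator
is *exactly* the linear-normal conditional model, which is what makes
the semianalytic size calculations testable against it. What it does
not emulate: measurement floors/censoring at small volumes, animal
dropout, heavier-than-lognormal tails, and treatment-by-time variance
heterogeneity. A green test on fixture data therefore establishes
correctness of the statistical machinery, not robustness to those
real-data features.

# Numerical choices

* Least squares via base QR (`qr`, `qr.coef`); $(X'X)^{-1}$ recovered
  from the triangular factor with pivot-order restoration. The explicit
  normal-equations solve exists only in the test suite as the
  independent oracle.
* Rank deficiency is detected (`qr$rank < 4`) and raised as an error —
  never silently pseudo-inverted.
* $p_{\text{two}} = 2\min(p_{\text{greater}}, p_{\text{less}})$, capped
  at 1; a zero SE with a zero estimate yields $t = 0$, $p = 1$; a zero
  SE with a nonzero estimate yields $t = \pm\infty$.
* Rendered reports round to 3 decimals; machine JSON/CSV output is full
  precision (`digits = NA`).

# Known limitations

* Single lag only, time moving forward; no multi-lag conditioning or
  cross-time p-value combination.
* The LMM comparator is random-intercept only (no AR(1)/unstructured
  residuals, no Satterthwaite/Kenward–Roger df); its default reference
  is the large-sample normal, with a residual-df $t$ as an option.
* No multiplicity adjustment across time points.
* The conditional-vs-marginal size behavior described above is intrinsic
  to the method, not a removable implementation detail.
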