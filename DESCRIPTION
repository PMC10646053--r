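Package: homotest
Title: Homologous Hypothesis Tests for Tumor Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-time-point comparison of mean tumor volumes between two
    treatment groups that gains efficiency by conditioning each group's
    outcome on its own lagged (previous time point) measurement through a
    four-parameter interaction regression, yielding a t test on n - 4
    degrees of freedom whose conditional variance shrinks by a factor of
    (1 - rho^2) relative to the standard cross-sectional two-sample t test.
    Includes the comparator procedures (pooled two-sample t test, linear
    mixed model with group-by-time interaction and random intercepts),
    closed-form noncentral-t power calculations, Monte-Carlo engines for
    type-I error and power studies under regression and compound-symmetry
    panel designs, a per-time-point analysis report, CSV input/output for
    wide and long repeated-measures layouts, a synthetic growth-curve
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
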