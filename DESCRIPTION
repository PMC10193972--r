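Package: chartrates
Title: Cross-Sectional Versus Longitudinal Rates of Change from Normative
    Centile Charts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how rates of age-related change inferred
    from cross-sectional normative centile charts (GAMLSS models with a
    Box-Cox t response) diverge from rates measured longitudinally, and for
    predicting individual follow-up phenotype values by integrating
    chart-derived rate-of-change curves. Includes a synthetic two-occasion
    cohort generator with known within-person slopes, birth-cohort effects
    and measurement noise (with closed-form oracles for the quantities the
    pipeline estimates), a penalized B-spline Box-Cox t centile fitter with
    bootstrap confidence bands and quantile-residual diagnostics, numerical
    differentiation and moving-average smoothing of centile curves,
    trapezoidal trajectory prediction with naive and age-permutation
    baselines, paired comparisons with FDR correction, and an end-to-end
    reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    mgcv,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
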