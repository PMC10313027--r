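Package: streamgamm
Title: Two-Step Generalized Additive Mixed Models for High-Frequency
    Water-Quality Sensor Time Series
Version: 0.1.0
Authors@R:
    person("streamgamm", "maintainers", email = "maintainers@streamgamm.org",
           role = c("aut", "cre"))
Description: Explains nitrate concentration in streams from co-measured
    water-quality sensor variables (specific conductance, dissolved oxygen,
    temperature, turbidity, surface-water elevation) using a two-step
    generalized additive mixed model: a penalized thin-plate-spline additive
    model with AIC-driven smoothing and stepwise variable selection, followed
    by an ARIMA model fitted to the additive-model residuals by exact Gaussian
    (Kalman filter) maximum likelihood with missing-value support. Includes an
    approximate-AIC model comparison criterion, leave-one-covariate-out
    variable importance by deviance decomposition, quality filtering and
    15-minute grid alignment of multi-rate sensor series, variance-inflation-
    factor screening, and a seeded synthetic sensor-data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
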