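# streamgamm

Two-step generalized additive mixed models (GAMMs) for explaining nitrate
concentration in streams from co-measured, high-frequency water-quality
sensor data.

## Who this is for

Freshwater scientists and water-quality managers who run in-situ sensor
arrays (nitrate plus conductance, dissolved oxygen, temperature, turbidity,
water level) and want to *explain* — not forecast — how nitrate relates to
the other variables, while accounting honestly for the strong serial
correlation of 15-minute data.

## The model

For nitrate $Y_i$ on a 15-minute grid and covariates $z_{ki}$ (including a
continuous time covariate):

$$Y_i = \beta_0 + \sum_{k=1}^m s_k(z_{ki}) + \eta_i, \qquad
\eta_i = \varepsilon_i + \sum_{j=1}^p \rho_j\,\eta_{i-j}
       + \sum_{l=1}^q \phi_l\,\varepsilon_{i-l},\qquad
\varepsilon_i \sim N(0,\sigma^2)$$

Each $s_k$ is a penalized thin-plate regression spline capped at 6
effective degrees of freedom. Estimation is in two steps: (1) the additive
model is fitted by penalized least squares with smoothing parameters and
the term set chosen by Gaussian AIC (bidirectional stepwise); (2) an
ARIMA$(p,d,q)$ model is fitted to the residuals by exact state-space
maximum likelihood (gaps handled exactly) and its order chosen by AIC over
$p \le 5$, $d \le 1$, $q \le 4$. Models with and without the error stage
are compared on the approximate AIC, $\mathrm{aAIC} = n\log\hat\sigma^2 +
2k$ (smaller is better), and covariate importance is the drop in total
deviance explained when that covariate is removed and the model refitted.

Supporting machinery: sensor-table readers with column dialects, quality
flag filtering, nearest-within-tolerance alignment to the nitrate grid,
log(turbidity + 1) transform, VIF screening (threshold 6), and a seeded
synthetic generator with known ground truth (diel/seasonal cycles, storm
pulses, ARMA errors, gaps, flagged anomalies) that stands in for the
restricted-access field data in every test.

## Worked example

Simulate a medium-nitrate stream (designed ground truth: conductance >
temperature > oxygen effects; turbidity, elevation, time null; ARMA(2,1)
errors), then run the full pipeline:

```r
library(streamgamm)

sdat <- simulate_dataset(scenario_spec("medium", seed = 42, n = 10000))
al   <- transform_covariates(
          align_to_response_grid(sdat$records, tolerance = 60,
                                 site = "synthetic-medium"))
vr   <- vif_screen(al, names(al$covariates))
gamm <- fit_gamm_two_step(al, vr$retained)
gamm
#> Two-step GAMM (synthetic-medium)
#>   additive stage:  specific_conductance + temperature + dissolved_oxygen + elevation + time   (deviance explained 80.7%)
#>   error stage   :  ARIMA(5,1,1)   (innovation variance 6.2)
#>   total deviance explained 83.7%, aAIC 17284.2 (k = 35.55)

compare_gam_gamm(gamm)
#>   model     aaic deviance_explained
#> 1   GAM 18747.00           80.67351
#> 2  GAMM 17284.22           83.69296

variable_importance(al, gamm)
#>              component importance
#> 1 specific_conductance  15.803392
#> 2          temperature  11.417419
#> 3     dissolved_oxygen   6.822511
#> 4                 time  -0.000544
#> 5            elevation  -0.011343
#> 6       autoregressive   3.019445

designed_deviance(sdat)   # ground truth: gam 80.6, total 83.3
```

Reading the numbers: the additive stage recovers 80.7% of the nitrate
variance (designed: 80.6%); adding the ARIMA error stage raises the total
to 83.7% (designed: 83.3%) and lowers the aAIC by ~1460, so the GAMM is
decisively preferred. The importance ranking reproduces the designed
effect ordering, and the three null covariates score ≈ 0.

A command-line wrapper ships in `inst/cli/streamgamm`
(`streamgamm simulate ...`, `streamgamm fit ...`) writing all tables as
CSV/plain text.

## Scope

No network access, no data downloads: all tests run on synthetic data with
known ground truth, and site-specific published values are not reproduction
targets. Figures are left to the user; every exported artifact is a table.
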