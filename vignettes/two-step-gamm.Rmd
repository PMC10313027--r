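---
title: "Explaining nitrate from co-measured sensor variables: a two-step GAMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining nitrate from co-measured sensor variables: a two-step GAMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamgamm)
```

## The problem and the model

In-situ optical sensors measure stream nitrate every 15 minutes, alongside
faster-cadence probes for specific conductance, dissolved oxygen, water
temperature, turbidity and surface-water elevation. The scientific question
this package addresses is explanatory, not predictive: how much of the
variation in nitrate concentration can be attributed to each co-measured
water-quality variable, once the strong serial dependence of
high-frequency data is accounted for?

The model is an additive mixed model with correlated errors,

$$Y_i = \beta_0 + \sum_{k=1}^{m} s_k(z_{ki}) + \eta_i,$$

where $Y_i$ is nitrate (μmol/L) at 15-minute time $i$, $z_{ki}$ are the
covariates (including a continuous time covariate in days), each $s_k$ is a
penalized thin-plate regression spline, and the error $\eta_i$ follows an
ARIMA$(p,d,q)$ process
$\eta_i = \varepsilon_i + \sum_j \rho_j \eta_{i-j} + \sum_l \phi_l
\varepsilon_{i-l}$ with $\varepsilon_i \sim N(0, \sigma^2)$ i.i.d.

Estimation is deliberately two-step:

1. **Additive stage.** `stepwise_select_gam()` fits
   $Y_i = \beta_0 + \sum_k s_k(z_{ki})$ by penalized least squares,
   ignoring serial correlation. Smoothing parameters and the set of
   included smooths are both chosen by the Gaussian AIC
   $n\log(\mathrm{RSS}/n) + 2(\mathrm{edf} + 1)$.
2. **Error stage.** `select_arma_order()` fits ARIMA models to the
   stage-one residuals by exact Gaussian maximum likelihood (state-space /
   Kalman filter) over the grid $p \le 5$, $d \le 1$, $q \le 4$ and keeps
   the AIC-best model.

Joint estimation of smooths and ARMA parameters is a stated non-goal: at
these data sizes joint optimizers routinely fail, and the two-step
procedure is the one being studied. Its known cost is that smoothing
parameters are selected as if errors were independent, so autocorrelation
can be partially confused with trend and the smooths can be slightly
undersmoothed; the error stage then absorbs what the smooths should not
have to. The df cap below is the main defence.

## Tunable parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `max_df` | 6 | Cap on each smooth's effective degrees of freedom. Large enough for intra-annual shapes, small enough not to chase sub-daily fluctuations that belong to the error process. Implemented structurally: the basis has rank 7, one dimension absorbed by the sum-to-zero constraint, so 6 is the exact maximum. |
| `threshold` (VIF) | 6 | Covariates with variance inflation factor at or above this are removed (greedy, worst first, recomputed each step) before modelling. |
| `tolerance` (alignment) | 60 s | Nearest-measurement matching window when placing covariates on the nitrate grid. The source data publish covariates at 1–5-minute cadence, so a coincident measurement exists whenever the sensor was up; 60 s accepts clock jitter without interpolating. |
| `p_max, d_max, q_max` | 5, 1, 4 | ARIMA search grid, covering the orders reported for real streams of this kind (up to AR 5, one difference, MA 4). |

Units: nitrate μmol/L, conductance μS/cm, oxygen mg/L, temperature °C,
turbidity FNU (modelled as log(turbidity + 1); natural log), elevation m.

## Numerical choices

* **Spline basis.** `mgcv::smoothCon()` builds the low-rank thin-plate
  regression spline (eigen-based rank reduction, curvature penalty,
  absorbed centering constraint). Eigen-reduction was preferred over
  quantile-knot placement because it is the canonical thin-plate
  construction and keeps the penalty null space (the linear trend) exact.
* **Smoothing-parameter search.** Each $\log_{10}\lambda_k$ is optimized
  coordinate-wise on a window of $\pm 8$ decades around a balance point
  $\lambda_{0k} = \mathrm{tr}(X^\top X)/\mathrm{tr}(S_k)$, cycling until
  the AIC changes by less than $10^{-6}$ (relative), at most 50 cycles.
  All per-candidate linear algebra runs on precomputed cross-products, so
  stepwise search never revisits the $n$-row design.
* **Identifiability.** Sum-to-zero constraints are absorbed into each
  basis, so partial effects are centered over the data and the intercept
  carries the level. Complete-case rows are defined by the full candidate
  set, which keeps AIC comparable across models during selection.
* **ARMA likelihood.** Exact Gaussian likelihood via a structure-exploiting
  Kalman filter (C++): stationary initialization from a Lyapunov solve,
  missing points skip the update step (exactly marginalizing them), and the
  filter switches to the steady-state recursion once the prediction
  covariance converges. With one difference, differencing is done within
  contiguous observed segments only; a difference across a gap is treated
  as missing. AICs are compared across the whole $(p,d,q)$ grid as a
  single ranking, with ties broken toward smaller $p+q$, then smaller $q$.
* **ARMA optimization.** Stationarity/invertibility are enforced by the
  partial-autocorrelation (tanh) transform. Starting values come from a
  Hannan–Rissanen regression, refined first on the cheap conditional
  sum-of-squares surface and then polished on the exact likelihood
  (BFGS); $\sigma^2$ is profiled out. The procedure is deterministic.
* **Selection guards.** Two field-standard rejection rules apply during
  order selection: fits with an AR or MA root within 1% of the unit circle
  are excluded (they encode spurious narrow-band cycles), and fits with an
  AR root within 0.05 of an MA root are excluded (near-common factors — the
  classical symptom of ARMA parameter redundancy). Without these, a
  thorough optimizer finds boundary optima on pure noise whose likelihood
  gain exceeds the AIC penalty, and selection over a wide grid
  systematically overfits. Even with the guards, plain AIC retains its
  textbook $\approx$ 15–30% chance of admitting one spurious low-order
  term on white noise; that is a property of AIC, not of the
  implementation.
* **Degenerate inputs.** Constant covariates are refused at basis
  construction; a constant (e.g. all-zero) residual series is flagged as
  degenerate rather than fitted; exactly collinear smooth designs raise an
  error that points at the VIF screen.

## The aAIC and model comparison

To compare the additive model with and without the error stage on one
scale, the package uses the approximate AIC,
$\mathrm{aAIC} = n \log(\hat\sigma^2) + 2k$: for the GAM alone,
$\hat\sigma^2$ is the residual variance and $k$ the total effective df;
for the combined model, $\hat\sigma^2$ is the ARIMA innovation variance
and $k$ adds $p + q$. Smaller is better. The convention fixed here (and
stated in every report header): $k$ counts the intercept inside the GAM's
effective df and does not count $\sigma^2$ itself; *total deviance
explained* is $100\,(1 - \mathrm{SS_{innov}}/\mathrm{TSS})$, where
$\mathrm{SS_{innov}}$ sums the squared standardized one-step prediction
errors of the final ARIMA fit. This one-step definition is what makes
"total deviance" of the combined model well-defined for a model that
explains by prediction; an in-sample smoother-plus-filter fit would give a
different (higher) number.

Variable importance is leave-one-covariate-out: the additive stage is
refitted without one term (same remaining terms, smoothing parameters
re-optimized; the stepwise search is *not* re-run), the ARIMA coefficients
are re-estimated at the full model's orders, and the importance is the
drop in total deviance explained. The autoregressive share is the gap
between total and additive-stage deviance explained. Re-selecting orders
per reduced model would confound importance with selection noise, which is
why the orders are held fixed. A known and documented consequence of this
definition: near-duplicate covariates mask each other (each one's
importance is near zero while their joint removal is large).

## What the synthetic world emulates — and what it does not

`truth_spec()` / `simulate_dataset()` generate the world the tests fit:

* **Covariates** = mean + diel sinusoid (24 h) + seasonal sinusoid
  (365.25 d) + AR(1) noise + storm pulses (instant rise, exponential
  decay); elevation shares its event times with turbidity, as storm flow
  does. Means and levels echo the published medians of three real streams
  (nitrate about 5.5 / 28.4 / 192 μmol/L across the low / medium / high
  scenarios).
* **True effects**: specific conductance (sigmoid, amplitude 6 μmol/L),
  temperature (sine, 4), dissolved oxygen (quadratic, 2); turbidity,
  elevation and time are genuine nulls. Shapes are applied to the
  standardized covariate and centered, so they are exactly what an
  identifiable additive model can recover; amplitudes are graded so the
  designed importance ordering is unambiguous.
* **Errors**: ARMA(2,1) with $\rho = (0.5, 0.3)$, $\phi_1 = -0.5$,
  $\sigma = 2.5$ by default. These values were fixed once, for
  identifiability: the negative MA component gives the process an ACF
  signature that pure-AR approximations cannot mimic, so order selection
  has a well-defined answer. The additive signal then carries roughly 80%
  of the variance, echoing the additive-stage share seen at real sites.
  The `persistent` scenario (AR(1) = 0.9, lag-1 autocorrelation 0.9)
  represents the strongly autocorrelated residuals real streams show, and
  is the setting in which the combined model must decisively beat the
  additive model on aAIC. The `iid` scenario gives the error stage nothing
  to absorb.
* **Gaps and anomalies**: response gaps come from a two-state Markov chain
  (geometric run lengths, default 5% missing with mean run 20, i.e. both
  isolated dropouts and multi-hour outages); anomalies (default 1%) are
  gross additive outliers carrying a quality flag, so the QC path is
  exercised end-to-end.

The generator does not attempt hydrological process realism: no
rainfall–runoff dynamics, no mass balance, no sensor drift, and
covariate–effect links are additive by construction. A green test
establishes that the estimation machinery recovers a known world of this
*form* at desk scale — it does not validate the ecological conclusions
drawn from any particular stream, and it cannot reproduce site-specific
numbers that depend on restricted field accessions.

## Known limitations

* Smoothing-parameter selection ignores autocorrelation (two-step
  structure); the df cap bounds, but does not remove, the resulting
  undersmoothing risk.
* The hard df cap has a flip side for uncertainty: once a smooth sits at
  the rank limit, the remaining error is basis-truncation bias, which the
  penalized-fit covariance does not count. The 2-SE bands then describe
  uncertainty *within* the rank-6 function space; for truths at the edge of
  that space (high precision, curvy shapes) their pointwise coverage can
  fall well below nominal even though the fit error itself is small. An
  mgcv fit with the same basis dimension shows identical behaviour.
* Stepwise selection with per-term AIC-optimized smoothing keeps one or
  more spurious terms on a pure-noise response in most replicates —
  adaptive flexibility hands each candidate its most favourable df. The
  same happens with an mgcv-based stepwise. Term selection is reliable for
  real effects, but a selected weak term is not evidence of one.
* AIC over a wide ARMA grid over-selects on near-null series with
  appreciable probability even with the root-based guards; selected orders
  should be read as "adequate", not "true".
* aAIC values computed under $d = 0$ and $d = 1$ involve slightly
  different effective series lengths; the grid ranking follows the raw
  values, which is the convention adopted here.
* Importance is defined only for covariates in the selected model, and
  masking under collinearity is inherent to leave-one-out definitions —
  run the VIF screen first.

## A worked run

```{r example, eval = FALSE}
library(streamgamm)

sdat <- simulate_dataset(scenario_spec("medium", seed = 42, n = 10000))
al   <- transform_covariates(
          align_to_response_grid(sdat$records, tolerance = 60))
vr   <- vif_screen(al, names(al$covariates))
gamm <- fit_gamm_two_step(al, vr$retained)

compare_gam_gamm(gamm)
variable_importance(al, gamm)
designed_deviance(sdat)   # the ground truth the fit should match
```
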