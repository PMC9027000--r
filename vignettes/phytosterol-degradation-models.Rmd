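---
title: "Modelling phytosterol degradation in bulk-stored rapeseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phytosterol degradation in bulk-stored rapeseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdeg)
```

## The problem

Total phytosterol content *PS* (mg g⁻¹ of seed) falls during bulk storage of
rapeseed, and the rate depends on the three variables that characterise a
storage ecosystem: seed water activity $a_w$, temperature $T$ and time
$\tau$. Direct determination of *PS* requires oil extraction, saponification
and chromatography, so a predictive model that maps the easily measured
$(a_w, T, \tau)$ to *PS* is the practical tool for storage management.
`psdeg` implements two such model families — a second-order response-surface
regression (RSR) and small feed-forward neural networks (MLP and RBF) — plus
the validation machinery used in predictive food microbiology to decide
whether a model is fit for use.

## The degradation surface and its assumptions

The RSR model is the full hierarchical quadratic in three predictors:

$$PS = \beta_0 + \beta_1 a_w + \beta_2 a_w^2 + \beta_3 T + \beta_4 T^2
     + \beta_5 \tau + \beta_6 \tau^2 + \beta_7 a_w T + \beta_8 a_w \tau
     + \beta_9 T \tau + \varepsilon .$$

Assumptions: additive i.i.d. Gaussian error, a smooth response over the
design region ($a_w \in [0.75, 0.90]$, $T \in [12, 30]$ °C, $\tau$ up to
72 days), and no terms beyond second order. All ten terms are kept — no
stepwise selection — matching the convention of keeping the hierarchical
model intact when every term is significant. The package ships the published
reference coefficient set (`reference_rsr_coefficients()`, stored exactly as
printed to 4 decimal places); under it the surface at $\tau = 0$,
$a_w = 0.75$, $T = 12$ is ≈ 7.0026 mg g⁻¹, and the time slope steepens with
$a_w$ through the negative $a_w \tau$ interaction — wet, warm bulks lose
phytosterols fastest.

## What the synthetic generator emulates — and what it does not

`build_storage_design()` crosses 4 temperatures with 4 water activities;
experiments run 72 days when $a_w \le 0.81$ and 48 days above (mould growth
ends the usable series earlier in wet bulks); one condition per temperature
is reserved for external validation (12 build + 4 validation experiments).
`simulate_degradation()` evaluates the surface at each (condition, time)
point and adds Gaussian noise per replicate.

Fixed choices, made once:

* **Sampling schedule: every 6 days, triplicate.** The source study never
  prints its measurement times, only that determinations were in triplicate;
  6-day spacing gives 13 points on the 72-day branch and 9 on the 48-day
  branch, a realistic chromatography workload. Configurable.
* **Noise sd 0.1 mg g⁻¹**, commensurate with a reported validation RMSE of
  ≈ 0.14 for the best network model. Configurable.
* **Truncation floor 10⁻⁶ mg g⁻¹** keeps *PS* strictly positive, which the
  log-scale metrics ($B_f$, $A_f$) require.
* **Water-activity levels {0.75, 0.80, 0.85, 0.90}** as the default cross;
  `storage_design_preset("exact")` provides the per-temperature levels that
  saturated-salt humidity control actually realises (0.76/0.86 etc.).

The generator emulates the *design structure* and the *surface plus noise*,
not real seed: it has no mould population dynamics, no moisture migration,
no replicate-correlated analytical error, and its "truth" is exactly the
quadratic surface. A green test therefore establishes that the estimators
recover a known data-generating process at realistic n and noise — not that
the quadratic form is the true chemistry of any particular seed lot.

## Data roles and the 243/108 split

Building data are divided 70:30 into learning and test sets;
four independent experiments form the validation set. The split operates on
*sampling points* (unique experiment × time), not raw rows, so the three
replicates of one determination can never straddle the learning/test
boundary — replicate leakage would make the test error an optimistic copy of
the learning error. The learning set receives
$\lfloor 0.7 \times n_{points} \rfloor$ points; with the canonical 117
triplicate building points this yields exactly 243 learning and 108 test
cases, i.e. shares of 51.9/23.1/25.0 % that round to 52/23/25 %. (A plain
row-level split rounded to the nearest integer cannot produce those counts
— `round(0.7 × 351) = 246` — which is why the group-floor rule was adopted.)

## Network models

Both families are 3-H-1 regressors on inputs and target min–max scaled to
[0, 1] with learning-set bounds (bounds are stored in the model and reused at
prediction time; conditions outside them are flagged as extrapolation).

**MLP.** Hidden activations: linear, logistic, exponential, tanh; linear
output. *Exponential* here is $e^x$, following the convention of the
commercial package whose "Exp" unit is a growing exponential; this is a
documented, configurable choice. Training minimises the scaled-target MSE by
BFGS with an analytic gradient; weights start uniform on [−0.5, 0.5] from a
recorded seed. The test-set error is monitored at every objective evaluation
and the returned network is the snapshot with the lowest test error seen —
the standard early-stopping guard against overfitting.

**RBF.** The named proprietary training algorithm has no public
specification, so the canonical two-stage fit is used instead: k-means
centres on the scaled inputs (seeded), per-centre widths equal to the mean
distance to the 2 nearest other centres, Gaussian units
$\exp(-\lVert x - c\rVert^2 / (2\sigma^2))$, and a ridge-regularised
($\lambda = 10^{-8}$) linear output layer. The ridge term only guards
against singular Gram matrices in the interpolation regime.

**Error definition.** "Learning/test/validation error" is the MSE on the
scaled target. The commercial software behind the reference study never
documents its error quantity, so absolute comparability of error magnitudes
is explicitly not claimed; selection only ever compares errors computed the
same way.

**Topology search.** Grids span H = 2–16 (MLP, per activation) and 2–50
(RBF), with `restarts` independently initialised networks per topology
(default 25 at desk scale; 1000 mirrors the reference protocol — the curves
average over restarts either way). Restart seeds are derived as
`base_seed + (topology − 1)·restarts + restart − 1`, so any individual
network can be reproduced in isolation. The best network minimises the
weighted error $w_L E_L + w_T E_T + w_V E_V$ with weights equal to the data
role shares (0.519/0.231/0.250 for the canonical counts); ties go to fewer
hidden nodes, then lower validation error. The five-cases-per-parameter
sizing rule $N_h = (L - 5N_{out})/(5(N_{in}+1+N_{out}))$ gives 9.52 for
L = 243 — the 9–10 node bracket.

## Validation suite

`compute_metrics()` implements, exactly as printed in the predictive
microbiology literature: MAE, RMSE, signed MRPE (over-prediction ⇒ negative,
because the numerator is $PS_E - PS_M$), MAPE, and the log-scale bias and
accuracy factors $B_f = 10^{\sum \log_{10}(PS_M/PS_E)/n}$,
$A_f = 10^{\sum |\log_{10}(PS_M/PS_E)|/n}$. Logs are base 10; the
$10^{(\cdot)}$ form makes the base cancel, base 10 is kept for readability.
R² is the coefficient of determination $1 - SS_{res}/SS_{tot}$ and is *not*
clamped — negative values are meaningful for models worse than the mean.
Useful identities, all property-tested: RMSE ≥ MAE, MAPE ≥ |MRPE|,
$A_f \ge \max(B_f, 1/B_f) \ge 1$; $B_f$ and $A_f$ are scale-invariant.

`ejcr_test()` regresses predicted on observed and forms the joint
$(1-\alpha)$ region
$\{\beta : (\beta-\hat\beta)^\top X^\top X (\beta-\hat\beta) \le 2 s^2
F_{1-\alpha}(2, n-2)\}$; the model is unbiased when the ideal point —
intercept 0, slope 1 — lies inside. (Different sources write the ideal pair
in both orders; field names, not ordering, carry the meaning here.) With
zero residual variance the ellipse collapses and containment degenerates to
exact equality of $\hat\beta$ with (0, 1). Under a true ideal model with
Gaussian noise the 95 % region covers the ideal point at exactly the nominal
rate, which the acceptance suite verifies by simulation (1000 replicates).

## Numerical choices

* Predictors are **not** centred or scaled for the RSR fit, so coefficients
  are directly comparable with the printed reference set; the resulting
  ill-conditioning ($T^2$, $\tau^2$ columns) is handled by pivoted QR, never
  normal equations. Noise-free recovery is exact to ≤ 10⁻⁶ relative error.
* p-values use the t distribution with $n - 10$ df — standard OLS inference.
* Model/report files are JSON at 17 significant digits, so a serialised
  model round-trips to bit-identical predictions.
* Every random stage takes a seed; the pipeline derives stage seeds from one
  master seed, making full reruns byte-identical.

## Known limitations

* The published per-dataset error tables and network-error magnitudes are
  not reproducible without the authors' raw measurements; the package
  replaces them with property-based checks (metric identities, EJCR
  coverage, planted-topology recovery) and the exactly reproducible
  reference-coefficient recovery.
* The generator's truth is the quadratic surface itself, so RSR enjoys a
  home-field advantage on synthetic data; network-vs-RSR rankings on
  simulated data say nothing about real seed.
* Single hidden layer only, linear output only — deliberate non-goals.
* The true measurement schedule of the source experiments (351 building rows
  over 12 experiments) is not inferable; the 6-day default is one plausible
  reconstruction, and the canonical 117-point layout used in tests is
  another.
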