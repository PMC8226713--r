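---
title: "Modelling thiol-group decay in stored minced meat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thiol-group decay in stored minced meat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiolkin)
```

## The problem

Free thiol (SH) groups on cysteine residues are progressively lost as meat
proteins oxidize during chilled storage, so the SH level — measured with
Ellman's reagent and expressed as a percent of the day-0 value — is a
convenient quality index for shelf-life work. `thiolkin` models SH decay in
minced meat (control plus thirteen plant-extract treatments, each raw and
cooked) stored at several constant temperatures, and predicts SH at
time–temperature combinations that were not measured.

## The kinetic model

At a fixed temperature the decay is treated as zero order,

$$\mathrm{SH}(t) = \mathrm{SH}_0 - k\,t,$$

with $\mathrm{SH}_0 = 100\%$ and $k$ in percent per day. Temperature enters
through the Arrhenius law,

$$k(T) = k_0 \exp\!\left(-\frac{E_a}{R\,T}\right),$$

with $k_0$ (day$^{-1}$) the pre-exponential factor, $E_a$ (kJ/mol) the
activation energy and $R = 8.314\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$, so
that $E_a/(RT)$ is dimensionless with $T$ in kelvin. $E_a$ is read here as
an empirical temperature-sensitivity parameter of a complex food matrix,
not as the barrier of a single elementary reaction. Temperatures are stored
in °C and converted internally with $T(\mathrm{K}) = T(°\mathrm{C}) +
273.15$, never rounded.

Two estimators are provided and both are reported:

* **Two-stage** (`fit_arrhenius_two_stage`): ordinary least squares of SH
  on $t$ at each temperature gives per-temperature rate constants; a second
  regression of $\ln k$ on $1/T$ gives $E_a = -R \times$ slope and
  $k_0 = e^{\text{intercept}}$. This is the classical linearization and the
  headline estimator.
* **Global** (`fit_arrhenius_global`): Levenberg–Marquardt nonlinear least
  squares of all observations of a group at once against
  $100 - k_0 e^{-E_a/(RT)} t$, via `minpack.lm::nls.lm`. The optimization
  runs over $(\ln k_0, E_a)$: the packaged reference parameters span
  $k_0 \approx 10^5$–$10^{22}$, and the log parameterization keeps $k_0$
  positive and the problem well-scaled without bounds. Initialization is
  the two-stage estimate; if that fails, $E_a = 60$ kJ/mol (mid-range of
  the reference table) with $k_0$ matched to the mean observed decay rate.
  Convergence: relative SSE change below $10^{-10}$ or 500 iterations.

On noiseless zero-order data the two estimators coincide; under noise they
answer the same question with slightly different weightings, so the
registry prints both. The per-temperature fits use a free intercept by
default (`fix_intercept = FALSE`), because the field practice is plain
linear regression of SH on time; a fixed-intercept mode (intercept pinned
at 100) is available since the model formally fixes
$\mathrm{SH}_0$. Replicates enter as individual points; an option averages
them per time point, because published tables of triplicate means do not
reveal which convention was used. Reaction order is checked with
`select_order`, which compares the $r^2$ of linear fits to SH, $\ln$ SH and
$1/\mathrm{SH}$ and breaks ties (within $10^{-9}$) toward the lower order —
ties arise naturally with two-point series, where all three transforms fit
exactly.

## The synthetic-data generator

`simulate_study` emulates the storage-study design: 14 treatments × 2 heat
states, sampling at 4, 8 and 12 °C over 13 days and at 16 and 20 °C over
5 days, in triplicate, with SH generated from the zero-order Arrhenius
surface plus additive Gaussian noise. Defaults, chosen once:

* **Generating parameters**: the 28 published $(k_0, E_a)$ pairs shipped in
  `reference_parameter_table()`.
* **Noise**: homoscedastic Gaussian on the percent scale with sd 2% — of
  the order of the triplicate scatter implied by published per-temperature
  RMSE values (roughly 1–13%, median near 4–5%, which bundle lack-of-fit
  with replicate noise, so the pure-noise sd sits at the low end).
* **Sampling grid**: daily within each temperature's storage span; the
  study reports only that samples were taken at appropriate intervals, so
  the densest plausible grid is used. Tests that loop over many seeds use a
  thinner grid (days 0, 3, 6, 9, 13 and 0, 1, 3, 5) to keep suites fast;
  the acceptance computation uses the full daily grid.
* **Negative values are kept**: a linear decay model crosses zero, and
  clamping would bias slope estimates near the end of the 20 °C series. A
  `clamp_zero` option exists for realism studies and is off by default.

The generator reproduces the statistical structure the estimators assume —
linear decay, Arrhenius rates, iid noise. Real meat data add lack-of-fit
(curvature, autocorrelated replicates, heteroscedasticity), so passing
recovery tests here demonstrates correctness of the estimation machinery,
not that real chicken obeys the model; the published per-temperature $r^2$
values (0.7–0.999) show how far real data deviate.

## The MLP ensemble

The neural route predicts SH from encoded storage conditions: a 14-column
one-hot treatment block, a 2-column heat-state block, and min-max scaled
time and temperature — 18 inputs on the full design. (The width is a
property of the encoding, not of the networks, which accept any input
width.) Each member is a one-hidden-layer perceptron with tanh, logistic or
exponential hidden units and tanh, linear or logistic output, trained by
full-batch BFGS (`stats::optim`) on the sum-of-squares error of the
min-max-scaled target, weights initialized uniform$(-0.5, 0.5)$ from a
seed so training is fully reproducible. The forward pass and analytic
gradient are implemented in the package; BFGS caps default to 300
iterations (observed quasi-Newton runs on this problem land in the
190–300 range). Only the sum-of-squares loss is implemented: the target is
continuous, so a cross-entropy classification loss does not apply.

`split_dataset` partitions the data 70:15:15 (train/validation/test) with
largest-remainder rounding; `search_architectures` trains a grid of
candidates, ranks them by validation error (ties broken by grid order) and
retains the best five; `ensemble_predict` averages the five members, which
can never be worse than the worst member under squared loss. Radial-basis
networks are not implemented: the retained architectures in the motivating
study are all MLPs.

## Treatment-effect regression

`fit_mlr` regresses SH on an intercept, 13 treatment dummies (control is
the uncoded reference), storage temperature (°C) and time (days),
untransformed so slopes read directly in percent per °C and percent per
day; raw and cooked meat are fitted separately. Classical homoscedastic
standard errors and two-sided $t$-tests against zero are used, with the
significance boundary inclusive at $p \le 0.05$. A positive dummy means SH
is preserved relative to control (antioxidant effect), a negative one
faster loss (prooxidant). The pooled-over-temperatures single model is the
default, matching the published analysis's implied structure.

The type-I-error check in the test suite generates its null data from
models with $E_a = 0$, so the true response surface ($100 - kt$, no
temperature effect, no treatment effect) lies inside the linear model
class and the nominal 5% level is the correct reference. Data curved in
$T\times t$ would load lack-of-fit into the residual variance and make the
dummy tests conservative — that would probe misspecification, not
calibration.

## Validation

`goodness_of_fit` reports $r^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (SST about
the observed mean), adjusted $r^2$ with $p = 2$ parameters for kinetic
models and the total weight count for ensembles, and
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/n}$ — denominator $n$, not $n - p$,
recorded in the report since the convention is not universal. Both plain
and adjusted $r^2$ are emitted because published validation statistics do
not say which they are. `external_validate` scores a predictor on the
hold-out temperature (12 °C by default) and refuses datasets whose
temperatures overlap the predictor's recorded training temperatures — a
guard against accidental leakage. `scatter_report` draws the
predicted-vs-observed scatter with the identity line.

## Numerical choices and degenerate inputs

* Per-temperature fits require ≥ 2 distinct times; the Arrhenius
  regressions require ≥ 2 distinct temperatures with positive rate
  constants (a non-positive fitted $k$ — possible under heavy noise for
  slow-decaying groups — is a hard error rather than a silently dropped
  point).
* Identical rate constants across temperatures return $E_a = 0$,
  $k_0 = k$ exactly.
* A single-temperature dataset makes $(k_0, E_a)$ unidentifiable and is
  refused.
* MLP losses that go non-finite (possible with exponential hidden units)
  are capped during line search; a run that ends non-finite raises a
  training-failure condition that `search_architectures` catches, dropping
  the candidate.
* The normalization baseline is the arithmetic mean of all replicate day-0
  values per (treatment, heat state, temperature) group — triplicates are
  summarized as means in this field, and per-replicate baselines are not
  recoverable from published tables.

## Problem sizes

The default simulated study is 4536 observations. The test suite fits all
28 groups noiselessly, runs 200-seed recovery checks for three reference
models on a thinned grid, and a 400-study type-I-error simulation; the
whole suite completes in well under a minute on a single CPU. The
acceptance computation averages 200 full-grid recoveries of the
cooked-garlic activation energy.

## Known limitations

* The kinetic model is empirical: no mechanistic coupling to lipid
  oxidation or microbial growth, no non-Arrhenius temperature models
  (Eyring, WLF), no dynamic (non-isothermal) storage profiles.
* Confidence intervals for $(k_0, E_a)$ are not provided; the registry
  reports point estimates and fit $r^2$ only.
* The MLR ignores the repeated-measures structure of a storage study;
  classical SEs understate uncertainty if replicate trajectories are
  autocorrelated.
* The generator's noise model is deliberately simple; conclusions about
  estimator behaviour under heteroscedastic or correlated noise require a
  different noise module.
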