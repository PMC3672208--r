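---
title: "Spatial structures, DIC averaging and kriging for chamber N2O fluxes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `n2ospatial`,
the assumptions behind them, and the design decisions taken where the
methodology left genuine choices open. It is the package's reference for
*why* things are computed the way they are; the README shows *how* to run
them.

## 1. The three regression models

All models act on log-transformed fluxes `y_ir = log(flux_ir + c)` for
chamber `i = 1..Q` and replicate `r = 1..M`. Chamber fluxes are strongly
right-skewed with occasional exact zeros, so the log transform is
essential and the shift constant `c` must be chosen: we use half the
smallest positive flux in the dataset when zeros are present and `c = 0`
otherwise. The constant is recorded in the dataset object and is
configurable; predictions are reported on the log scale, with a lognormal
back-transform available for surfaces.

The linear predictor is `β₀ + xᵀ_ir β` with the K = 7 covariates in a fixed
canonical order: gravimetric moisture (%), soil temperature (°C), NO₃⁻
(kg N ha⁻¹), pH, sand, silt, clay (%). The three models differ only in the
site-level term added to this predictor:

* **independent** — none; residuals `ε_ir ~ N(0, σ²)` iid.
* **exp (geostatistical)** — `s_i` from a zero-mean stationary, isotropic
  Gaussian process with `Cov(s_i, s_j) = σ²_s exp[−(θ d_ij)^δ]`, `δ = 1`.
  `θ` (units 1/m) is the decay rate of spatial correlation: large `θ`
  means short-range correlation.
* **icar** — `u_i` with the intrinsic conditional autoregressive prior
  `u_i | u_{−i} ~ N(Σ_j w_ij u_j / w_i+, σ²_u / w_i+)` on the binary
  first-order Thiessen neighbourhood matrix `W`.

Replicates within a chamber share one site effect and are otherwise
exchangeable: the site effect is indexed by site only, and residuals are
iid across sites and replicates. No temporal correlation between monthly
replicates is modelled — that is a deliberate scope decision (see §6).

### Priors

* `β_k ~ N(0, 10⁶)` for every coefficient including the intercept.
* `σ ~ U(0, 5)` on the *standard-deviation* scale.
* `σ_u ~ U(0, 10)`; `σ_s ~ U(0, 10)`. The uniform prior for the
  geostatistical process SD is our own choice by symmetry with the ICAR
  prior — the methodology we follow specifies the ICAR bound explicitly
  but is silent on `σ_s`.
* `θ ~ U(θ_lo, θ_hi)` with `θ_lo = −ln(0.05)/d_max` and
  `θ_hi = −ln(0.05)/d_min`: at the prior bounds, the correlation at the
  largest (smallest) observed inter-chamber distance equals 0.05. For the
  emulated field (`d_min = 0.75` m, `d_max = 25.35` m) this gives
  `(0.118, 3.994)`.

Sampling `σ`, `σ_s`, `σ_u` directly on the SD scale by slice sampling
within the prior bounds avoids any Jacobian bookkeeping against the stated
uniform priors; the slice sampler shrinks from the full support interval,
which is valid because the support is bounded.

## 2. MCMC

Each fit runs a single chain. Production defaults follow common practice
for these models: 150,000 iterations, 50,000 burn-in, thinning 10 (bounded
memory at ~10,000 retained draws). Updates per iteration:

* `β` — multivariate-Normal full conditional via Cholesky of
  `XᵀX/σ² + I/10⁶`.
* `s` (exp) — joint Gaussian full conditional with precision
  `Φ⁻¹/σ²_s + (M/σ²) I` (replicates are balanced, so the data precision is
  diagonal).
* `θ` (exp) — random-walk Metropolis on its uniform support. The proposal
  SD is adapted every 50 iterations during burn-in toward a 20–50%
  acceptance rate and frozen afterwards, preserving detailed balance for
  the retained draws.
* `u` (icar) — single-site Gibbs updates: each conditional blends the
  neighbour-average prior (precision `w_i+/σ²_u`) with the site's
  likelihood term (precision `M/σ²`). Sites are processed in colour
  classes of the neighbourhood graph (greedy colouring), which batches
  mutually non-adjacent sites into one vectorised draw without changing
  any conditional. After every sweep `u` is recentred to sum to zero —
  the standard identifiability device for the improper intrinsic prior,
  with the intercept retained in the model.
* `σ`-family — slice updates as above.

Degenerate designs: an exactly singular design matrix is an error naming
the collinear columns, with one deliberate exception — the
sand + silt + clay ≈ 100 texture identity (exact after the generator's
renormalisation). That near/exact collinearity is allowed through because
the Normal prior keeps the posterior proper; its footprint is the familiar
one of texture coefficients with very wide credible intervals, while
identified directions (moisture, temperature, NO₃⁻) are unaffected.

Numerical safeguards: correlation matrices get an escalating diagonal
jitter (starting at 1e-8 of the mean diagonal) on Cholesky failure;
`exp(−θd)` with `δ = 1` is positive definite in exact arithmetic, so the
jitter is a pure floating-point guard.

### Convergence

`convergence_report()` gives per-parameter lag autocorrelations, an
effective sample size from the empirical ACF truncated at its first
non-positive lag, and a split-chain z-statistic comparing the two
half-chain means with ESS-adjusted standard errors. Constant chains are
flagged degenerate with an undefined ESS. `plot_traces()` writes trace and
ACF panels.

## 3. Deviance, DIC and model averaging

The deviance is `D = −2 Σ_ir log N(y_ir | μ_ir, σ²)` with `μ_ir` including
the site effect — i.e. *conditional* on the latent effects. This is the
random-effects-focused deviance that standard MCMC software reports for
these hierarchical models, and the DIC (and hence the averaging weights)
inherits that convention; a marginalised focus would give different `pD`
and DIC values. `Dbar` is the mean of the per-iteration deviance trace,
`D_at_mean` re-evaluates the deviance at the posterior means of all
parameters entering the likelihood, `pD = Dbar − D_at_mean`, and
`DIC = Dbar + pD`.

Posterior model probabilities use the information-criterion approximation
with equal 1/3 priors by default:
`p(M_l | D) ∝ p(M_l) exp(−DIC_l/2)`. With DIC values in the hundreds the
exponentials underflow, so weights are computed in log space with
max-subtraction — a shift-invariant, loss-free stabilisation.

The averaged posterior predictive is defined as the *mixture* of per-model
predictive distributions, not an average of summaries: `bma_combine()`
resamples predictive draws from each model in proportion to its weight
(largest-remainder allocation, so a weight of exactly 1 returns that
model's draws unchanged) and reports the mixture mean analytically as
`Σ_l w_l mean_l`. Mixture quantiles therefore include between-model
spread, consistent with the law of total variance.

## 4. Geometry: Thiessen neighbourhoods

`thiessen_adjacency()` constructs each site's Voronoi cell by successive
half-plane clipping of a boundary rectangle (Sutherland–Hodgman) and sets
`w_ij = 1` exactly when two clipped cells share an edge of length
> 1e-9 m. Design choices:

* **Boundary**: field layouts rarely publish the polygon clipping frame.
  Default: the coordinate bounding box expanded by 10% per side
  (configurable). Adjacency among interior sites is insensitive to modest
  margin choices; only peripheral adjacencies that exist purely beyond
  the margin can differ.
* **Point-contact cells**: four cells meeting at a point (e.g. the
  corners of a square) are *not* neighbours — "sharing a boundary" is
  read as a positive-length edge, tie-broken by the 1e-9 m threshold.
* **Collinear layouts**: a strict 2-D tessellation is degenerate; the
  package falls back to chain adjacency along the dominant direction with
  a warning.
* Coordinates are planar metres; no geodesy.

The test suite checks this construction against an independent
brute-force oracle that samples densely along each pair's perpendicular
bisector and asks whether a positive-length stretch inside the boundary
is nearest to exactly that pair.

## 5. Prediction and kriging

`posterior_predict()` draws predictive replicates `μ_ir + N(0, σ²)` per
retained draw; observation-level 95% intervals support the
fraction-outside coverage check and the sum of squared residuals, and
site-level summaries average the replicates within each draw.

Kriging follows the workflow of interpolating *model predictions* rather
than raw data: the site-level posterior summaries (and, for the spatial
models, the posterior-mean site effects — the "spatial variation"
surface) are kriged once onto a regular grid, default resolution 0.5 m.
Per-draw kriging for full uncertainty propagation is possible by calling
`krige()` on individual draws, but the default mirrors the
summarise-then-interpolate practice. The BMA surface kriges the mixture
site means, i.e. mixture-then-krige; because ordinary kriging is linear
in the data, this equals the weight-mixture of per-model kriged surfaces.

The variogram is an exponential model
`γ(h) = nugget + psill (1 − exp(−3h/range))` (`range` = practical range)
fitted to a binned method-of-moments empirical semivariogram by weighted
least squares with pair counts as weights, multi-started over three
initial ranges. Identifiability tie-break: a flat (pure-noise) empirical
variogram is equally well fitted by a pure nugget or by a tiny-range
exponential; when the fitted range collapses onto its lower bound (the
first resolvable lag), the structural sill is folded into the nugget. A
constant field short-circuits to a degenerate zero-sill pure-nugget model.
Ordinary kriging solves the standard semivariogram system with the
`Σλ = 1` unbiasedness constraint; weight sums are asserted to machine
precision and tiny negative variances are clamped at zero.

## 6. The synthetic-data generator

The generator emulates the study design the models target: Q = 17
chambers placed uniformly at random (rejection-sampled to a 0.75 m
minimum separation) in a 16.5 m × 16.5 m field (~272 m², giving pairwise
distances up to the ~23 m diagonal), M = 13 monthly replicates, and
covariates matched to published summary moments (`table1_moments()`).

* Moisture and temperature share a standardised sinusoidal seasonal
  signal across the monthly replicates (12-month period), with variance
  split 50% seasonal / 25% site / 25% residual — monthly sampling over a
  year implies seasonality, and recovery tests need within-site covariate
  variation. Values are clipped to the observed ranges.
* NO₃⁻ is Gamma-distributed with the target mean/SD: right-skewed and
  non-negative, where a clipped Gaussian would pile mass at zero and bias
  the mean.
* pH and texture are site-static; texture triplets are renormalised to
  sum to exactly 100 (skipped in the degenerate all-SDs-zero mode so that
  zero-noise draws reproduce the means exactly).
* Log-fluxes are generated from the fitted-model form itself:
  `β₀ + xᵀβ + effect + ε`. Default coefficients are realistic
  posterior-scale values for pasture flux regressions
  (e.g. +0.039/moisture %, +0.15/°C on the log scale), with
  `σ² = 2.0` (independent) or `1.59` plus `σ²_s = 0.76, θ = 1` (exp) or
  `σ²_u = 1.78` (icar). A configurable `back_shift` subtracts a constant
  on the natural scale and floors at zero, producing occasional exact
  zeros to exercise the log-shift path.
* Determinism: every stage draws from a sub-seed derived from the master
  seed and a stage label, so identical seed + config gives byte-identical
  CSVs while stages remain independently re-runnable.

What the generator does *not* emulate — and hence what passing tests do
not establish about field data: temporal autocorrelation of fluxes
between months (replicates are iid given the site effect, as the model
family assumes), covariate measurement error, hot-spot/hot-moment
dynamics beyond what a lognormal residual produces, and anisotropy.
Recovery results on synthetic data show the samplers are correct, not
that the model family is adequate for any particular field.

## 7. Test problem sizes

The suite exercises the full study dimensions (Q = 17, M = 13) but with
chains scaled to 15,000/5,000 (recovery coverage, 20 seeds per structure)
and 6,000/2,000 (DIC model-selection replications, 10 seeds) — a tenth of
the production run, chosen so the whole suite completes in minutes while
leaving Monte-Carlo error well below the tolerances asserted. Production
analyses should use the 150,000/50,000 defaults.

## 8. Known limitations

* DIC (and therefore the averaging weights) is convention-dependent: the
  conditional deviance focus is stated above, and comparisons against
  DIC values computed under a marginal focus are not meaningful.
* The ICAR variance `σ²_u` is weakly identified at Q ≈ 17; its posterior
  is prior-sensitive and recovery is only reliable to within a factor of
  a few.
* The Thiessen boundary rectangle is a modelling construction; adjacency
  of peripheral sites can depend on the margin.
* Kriged surfaces interpolate posterior summaries; their variance layer
  reflects interpolation uncertainty about the summary, not full
  posterior predictive uncertainty.
* Single-chain diagnostics only; no cross-chain R-hat workflow.
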