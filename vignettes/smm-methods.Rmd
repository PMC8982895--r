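---
title: "Semiparametric mixed models with Lasso basis selection: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiparametric mixed models with Lasso basis selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smmlasso)
```

## The model

For mouse `i` (group `g_i` ∈ {0, 1}, allograft = 0, autograft = 1) measured
at days `t_ij`, `j = 1…n_i`,

$$y_{ij} = \beta_0 + \beta_1 g_i + f_{g_i}(t_{ij}) + \varphi_i +
\varepsilon_{ij}, \qquad \varphi_i \sim N(0, \sigma_\varphi^2), \quad
\varepsilon_{ij} \sim N(0, \sigma^2).$$

`β₀` is the mean level of the reference group, `β₁` the group contrast,
`φ_i` a subject-level random intercept shared across that mouse's visits,
and `f_g` an unknown group-specific time effect. The assumptions that
matter in practice: a *single* additive random intercept (no random
slopes), homoscedastic Gaussian noise (longitudinal optical data often
show variance growing with time — this model ignores that), and smooth
`f_g` expressible in a fixed dictionary.

`f_g` is expanded over M candidate functions ψ₁…ψ_M evaluated on days
affinely rescaled to [0, 1]:

* cubic B-splines with interior knots at empirical quantiles of the
  observed days (k knots → k + 4 functions),
* Fourier pairs `sin(2πjs), cos(2πjs)`,
* powers `s, s², …`,
* Haar indicators of dyadic intervals at levels 1…L.

Defaults: 8 knots, 4 pairs, 2 powers, 3 Haar levels → M = 36. The constant
function is excluded — it is exactly confounded with `β₀` (and, between the
two blocks, with `β₁`), and keeping it would make the least-squares step
for `β` meaningless. The coefficient vector λ has length 2M: block 1 is
active on allograft rows, block 2 on autograft rows.

## Identifiability

`β₀ + β₁ g + f_g(t)` is invariant to shifting each `f_g` by a constant and
adjusting `β`. No centering constraint is imposed on the estimate — the
L1 penalty is what discourages constant-like components in `f̂_g` (constants
are cheaper in the unpenalized `β`). Two consequences:

* at γ = 0 nothing disambiguates the split; with a dictionary fine enough
  to saturate every (group, day) cell the estimate of `f_g` is the cell
  mean and the group coefficient is driven to zero. Such fits are flagged
  (`identified = FALSE`): the zero is an artifact of the decomposition, not
  evidence of no effect;
* `β̂₁` equals the generative `β₁` only if the truth allocates constants
  the same way. The synthetic-data generator therefore centers the true
  `f_g` over the measurement schedule (the convention used for smooths in
  additive models), making `β₀`/`β₁` the population mean levels and
  parameter recovery a well-posed question.

## The penalized EM algorithm

Per iteration, in this order:

1. **E-step.** With `η = σ²/σ_φ²`, the conditional variance and mean of the
   intercepts given the residual `r = y − Xβ − Fλ` are
   `W_i = σ²/(n_i + η)` and `φ_i = (W_i/σ²) Σ_j r_{ij}` — the standard
   random-intercept BLUP. `σ_φ² = 0` gives the degenerate branch `φ = 0`,
   `W = 0` rather than an error.
2. **M-step.** `σ_φ² = (1/N) Σ_i [φ_i² + σ²/(n_i + η)]` and
   `σ² = (1/n)[Σ_i ‖Ê_i‖² + Σ_i n_i σ²/(n_i + η)]` with
   `Ê = y − Xβ − Zφ − Fλ`.
3. **Weighted Lasso.** `λ` minimizes
   `(1/n)‖u − Fλ‖² + 2σ² Σ_k r_{n,k}|λ_k|` with `u = y − Xβ − Zφ` and
   `r_{n,k} = ‖ψ_k‖_n γ √(log(2M)/n)`; the empirical norm
   `‖ψ_k‖_n² = (1/n) Σ_{ij} ψ_k(t_ij)²` sums over *all* mice regardless of
   group, and both blocks share the same norm.
4. **Least squares.** `X'Xβ = X'(y − Fλ − Zφ)`; standard errors from
   `s²(X'X)⁻¹`, `s² = RSS/(n − 2)`; two-sided t tests on n − 2 degrees of
   freedom (two fixed-effect columns; the degrees of freedom behind the
   published tables are not stated, so the classical choice is used).

A control switch (`subtract_beta = FALSE`) provides the variant in which
the E-step and M-step residuals omit `Xβ` (i.e. `y − Fλ` and
`y − Zφ − Fλ`). It is not the default: without subtracting the fixed
effects, the intercept BLUPs absorb the population mean and `σ_φ²`
estimates level-plus-heterogeneity rather than between-mouse variance. The
default is the standard EM for this model; both variants are available for
comparison because published formulations differ on this point.

### Initialization

`β₀` starts at the grand mean and `β₁` at zero; with a saturating
dictionary this makes the γ = 0 group coefficient exactly zero at every
iteration, matching the degenerate-case analysis above. The variances start
from an ANOVA-style decomposition: `σ_φ²` from the between-mouse variance
of the mouse means (centered within group), `σ²` from the residual variance
of a two-way fit on mouse and (group, day) cells. The second choice is
deliberate: a pooled within-mouse variance would include the time-effect
variance, and because the Lasso threshold scales with `σ²`, an inflated
initial `σ²` can make the all-zero coefficient vector an *absorbing* state
(nothing activates, so `σ²` never decreases). For the same reason the EM
loop is entered with a one-pass warm start: a single weighted-Lasso solve
at the initial variances, followed by one least-squares pass for `β`, so
that the first E-step sees residuals free of the fixed effects and of the
initial time-effect estimate. Without that pass, the first E-step hands the
unexplained group contrast to the intercepts, which is both a biased start
and, in low-noise data, a self-consistent degenerate fixed point.

### Numerical choices

* **Inner solver.** Cyclic coordinate descent with soft-thresholding
  (compiled), warm-started from the previous EM iteration (and from the
  previous grid point inside γ sweeps). Stops when the largest coefficient
  change in a sweep is ≤ 1e−8, with a cap of 1e5 sweeps; if the cap is hit
  the iterate is accepted when its KKT stationarity violation is ≤ 1e−6
  (flat directions of collinear dictionaries — e.g. powers inside the
  spline span at γ = 0 — stall the change-based criterion long after
  stationarity holds) and is an error otherwise.
* **Outer convergence.** Largest relative parameter change across
  (β, λ, σ², σ_φ²) ≤ 1e−6 (per block: `max|Δ| / (1 + max|old|)`), capped at
  500 iterations.
* **Variance floors.** `σ²` and `σ_φ²` are floored at 1e−12 (`σ_φ²` with a
  warning) so the E-step stays defined on noiseless or degenerate data.
* **Ties and extrapolation.** Duplicate (mouse, day) rows are an error, not
  averaged. Evaluating the dictionary outside the training day range warns;
  spline values are clamped to the boundary, analytic families extrapolate.

## The tuning parameter γ

γ ≥ 0 scales the penalty; larger γ means fewer active basis functions and
smoother fitted trajectories. There is no automatic selector — published
practice for this estimator is to sweep a grid (0 to 2 in steps of 0.05),
inspect the group coefficient, its significance boundary
(`t_{1−α/2, n−2}·SE(γ)`), active-set size and in-sample RMSE, and choose
visually; 0.5 is a common middle choice and is the package default. The
sweep report annotates rather than selects.

One property of the printed penalty deserves emphasis: the threshold is
`2σ² r_{n,k}`, i.e. it scales with the residual *variance*, not the
residual SD. On responses of large numeric scale (THC in μM, σ ≈ 5,
σ² ≈ 25) moderate γ can shrink every coefficient to zero, whereas after
baseline normalization (rTHC ≈ 1, σ² ≈ 0.01) the same γ leaves dense fits.
The formula is implemented as printed; users fitting raw-scale responses
should expect to need smaller γ than for normalized ones, and the γ sweep
is the instrument for seeing where the active set vanishes.

## The synthetic-data generator

`sim_config()`/`simulate_dataset()` emulate the motivating study design:
two groups of 6 mice (cohort sizes were not published; 6 per group is a
realistic single-lab cohort), schedule `{−1} ∪ {7…14} ∪ {17, 21, 24, 28,
31, 35, 38, 42, 44}` (baseline, daily week 2 after excluding the
contaminated first week, then twice-weekly), `β = (143.4, 4)` μM on the
scale of the published intercept, `σ = 5`, `σ_φ = 5`, optional independent
Bernoulli dropout that never removes the baseline. True time effects come
from closed-form templates — `plateau` (rise then flatten, the allograft
pattern), `rise` (still increasing at day 44, the autograft pattern),
`linear`, `zero` — centered over the schedule as discussed above.

What the generator does *not* emulate: heteroscedasticity (variance growing
with time, visible in the motivating data), informative missingness, and
measurement error from the upstream image ROI averaging. Passing recovery
tests therefore demonstrate correctness of the estimator under its own
assumptions, not robustness to these violations. An honest caveat on
inference: the least-squares standard error of `β̂₁` conditions on the
fitted `f` and `φ` and ignores both selection and between-mouse
uncertainty; in the default recovery experiment the Monte-Carlo SD of
`β̂₁` (≈ 2.8 with 6 mice per group and `σ_φ` = 5) is several times the
reported SE, so the group test is anticonservative at small N. The
recovery report prints the empirical rejection rate so this is measurable
rather than hidden.

## Problem sizes used in the shipped experiments

The recovery experiments run 100 replicates of the default design (n = 216
observations, M = 36, one fit per replicate) at γ = 0.5, plus 100 at
σ = 2.5; the degenerate-γ checks use one simulated dataset with a
saturating level-6 Haar dictionary (128 columns). These sizes give
Monte-Carlo standard errors ≈ 0.28 on the mean group effect — small enough
to detect biases of half a standard error — while keeping a full run in a
few minutes on one core.

## Known limitations

* The σ²-scaled penalty couples smoothing strength to the response scale;
  comparisons of γ across responses require normalization.
* No REML, random slopes, or heteroscedastic residual model.
* Standard errors are post-selection-naive (see above).
* γ is chosen by inspection; no data-driven criterion is provided.
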