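# smmlasso

Semiparametric mixed-effects models with Lasso basis selection for
longitudinal data.

## What this package is for

Longitudinal monitoring studies — the motivating case is non-invasive
optical imaging of hemodynamics (total hemoglobin concentration, THC, in
μM; blood oxygen saturation, StO₂) over the course of bone-graft healing in
mice — produce repeated measures per subject on an uneven time grid: a
pre-surgery baseline at day −1, daily measurements in week 2, then roughly
twice-weekly visits to day 44. A linear mixed model (LMM) forces a linear
time trend; treating time as categorical forfeits prediction between
visits. The semiparametric mixed-effects model (SMM) keeps time continuous
and lets the data pick the shape of the time effect:

    y_ij = β₀ + β₁ g_i + f_{g_i}(t_ij) + φ_i + ε_ij

where `g ∈ {0, 1}` codes the treatment group (allograft = 0, autograft = 1),
`φ_i ~ N(0, σ_φ²)` is a per-mouse random intercept, `ε_ij ~ N(0, σ²)` is
residual noise, and `f_g` is an unknown group-specific time effect
represented as a sparse combination of a dictionary of M candidate basis
functions ψ₁…ψ_M (cubic B-splines, Fourier pairs, powers, Haar steps).

Estimation is a closed-form penalized EM algorithm. Each iteration:

1. **E-step** — BLUP of the random intercepts:
   `W_i = σ²/(n_i + η)`, `φ_i = (W_i/σ²)·Σ_j r_ij`, with `η = σ²/σ_φ²` and
   `r` the residual after the current fixed and time effects.
2. **M-step** — variance updates
   `σ_φ² = (1/N) Σ_i [φ_i² + σ²/(n_i + η)]`,
   `σ² = (1/n) [Σ_i ‖Ê_i‖² + Σ_i n_i σ²/(n_i + η)]`.
3. **Weighted Lasso** — coefficients λ (length 2M, one block per group) solve
   `min (1/n)‖u − Fλ‖² + 2σ² Σ_k r_{n,k} |λ_k|`,
   `r_{n,k} = ‖ψ_k‖_n · γ · √(log(2M)/n)`,
   by cyclic coordinate descent with soft-thresholding (compiled inner
   solver; warm-started).
4. **Least squares** — `β` from `X'Xβ = X'(y − Fλ − Zφ)` with classical
   t-based inference.

The tuning parameter γ controls smoothness: γ = 0 saturates the data
(the group effect is then unidentified and estimated as 0), large γ returns
an almost-straight line; a grid sweep over [0, 2] with the per-γ group
effect, its significance boundary, and a fit-versus-smoothness report is
built in, along with an LMM baseline fit by the same EM machinery and a
synthetic-data generator for parameter-recovery experiments.

## Worked example

```r
library(smmlasso)

# simulate the default study design: 6 mice per group, days
# {-1, 7..14, 17, 21, 24, 28, 31, 35, 38, 42, 44}, beta = (143.4, 4),
# sigma = 5, sigma_phi = 5
sim <- simulate_dataset(sim_config(seed = 42))
fit <- fit_smm(sim$data, control = smm_control(gamma = 0.5))
print(fit)
#> Semiparametric mixed-effects model (gamma = 0.5 )
#>   response: THC  n = 216  mice = 12
#>    converged after 10 EM iterations
#>   sigma2 = 37.39  sigma2_phi = 15.16  active basis coefficients: 0
#>
#>         term   estimate std_error    t_value       p_value
#>  (Intercept) 143.655788 0.5764802 249.194665 1.180546e-265
#>        Group   3.271892 0.8152661   4.013281  8.280774e-05
```

The `Group` row is the autograft-vs-allograft contrast in mean level
(truth: 4 μM in this simulation; the estimate differs from the truth by the
realized random intercepts of these 12 mice). On this draw the penalty at
γ = 0.5 shrinks every basis coefficient to zero — with σ ≈ 5 the
σ²-scaled penalty is severe, a behaviour discussed in the methods
vignette — so `sigma2` also absorbs the unexplained time effect. A γ sweep
and the linear baseline:

```r
sw  <- gamma_sweep(sim$data)          # 41 fits on the 0:2:0.05 grid
plot_gamma_sweep(sw)                  # group effect vs gamma + 5% boundary
lmm <- fit_lmm(sim$data)
compare_fits(fit, lmm)                # estimates, variances, in-sample RMSE
```

Command-line front end over the same functions:

```sh
Rscript inst/cli/smm-cli.R simulate --seed 1 --outdir out
Rscript inst/cli/smm-cli.R fit --input out/simulated.csv --response value --outdir out
Rscript inst/cli/smm-cli.R sweep --input out/simulated.csv --response value --gamma-grid 0:2:0.05 --outdir out
```

## Package layout

- `R/data_io.R` — validated long-format datasets, CSV loading, baseline
  normalization (rTHC/rStO₂), time-window filtering
- `R/basis.R` — basis dictionary, empirical norms, penalty weights, block
  design matrices
- `R/smm.R` — penalized EM estimator (E/M steps, weighted Lasso,
  least-squares inference), prediction, time-effect reconstruction
- `R/lmm.R` — the linear mixed-model baseline and model comparison
- `R/gamma.R` — γ sweep, significance boundary, smoothness report, plots
- `R/simulate.R` — synthetic-data generator and recovery experiments
- `R/pipeline.R`, `inst/cli/smm-cli.R` — configuration-driven runs
- `src/cd_lasso.cpp` — compiled coordinate-descent inner solver
- `vignettes/smm-methods.Rmd` — the model, its assumptions, and the
  numerical choices
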