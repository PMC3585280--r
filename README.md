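# rbcwarmup

Analysis of red blood cell concentrate (RBC) warm-up by proton resonance
frequency (PRF) MR thermometry. When an RBC unit leaves 1-6 °C storage its
temperature field becomes non-uniform: the surface warms immediately, the
core lags. `rbcwarmup` turns phase-difference image series into temperature
maps, extracts mean, surface and core temperature time courses, fits compact
analytical warm-up models, and converts the fitted constants into cold-chain
quantities relevant to transfusion practice (the "30-minute rule", the 10 °C
core limit). It is aimed at blood-bank quality-control and MR-thermometry
researchers.

## The model

With the relative temperature difference
θ = (T_ambient − T)/(T_ambient − T_storage), the mean RBC temperature
follows a lumped-capacitance decay and surface/core temperatures follow
shifted exponentials:

    θ_mean(t)    = exp(−t/τ_mean)
    θ_surface(t) = exp(−(t/τ_surface + Δ_surface))
    θ_core(t)    = exp(−(t/τ_core − Δ_core))

The spread θ_core − θ_surface is maximal at
t* = [ln(τ_s/τ_c) + Δ_s + Δ_c] / (1/τ_c − 1/τ_s), and eliminating time
yields geometry-robust predictions of mean and core state from the surface
state. Fitting is Levenberg-Marquardt nonlinear least squares with
log-linear initialisation; parameter SDs propagate to curve bands by
first-order Gaussian error propagation.

Because no scanner data ship with the package, a finite-difference pouch
phantom (heat equation with convective boundary, PRF phase encoding with
shared scanner drift, reference phantoms and Gaussian noise) generates
everything the pipeline consumes, and analytic oracles (lumped closed form,
1-D slab Fourier series, energy balance) back the solver.

## Worked example

```r
library(rbcwarmup)

# cohort-mean constants for leukoreduced RBC units in SAGM
fit <- cohort_reference_fit()
theta_shifted_model(30, fit$tau_core, fit$delta_core, "core")
#> [1] 0.7042478
limit_ambient(1, 30, 10, fit, "core")
#> [1] 31.43088
time_to_threshold(10, 1, 20, fit, "core")
#> [1] 52.36638
t_spread(fit)
#> [1] 45.62016
theta_spread(t_spread(fit), fit)
#> [1] 0.2648729
```

Read: 30 min after leaving storage the core has covered only 30 % of the way
to ambient (θ_core = 0.70); with 1 °C storage the core stays below 10 °C for
30 min up to a 31 °C room; at 20 °C ambient the core needs 52 min to reach
10 °C; the core-surface spread peaks near 46 min at 26 % of the
storage-to-ambient span.

End-to-end on synthetic images:

```r
report <- run_unit(seed = 1L)   # simulate -> encode -> decode -> extract -> fit
print(report)
#> Unit analysis report (seed 1 )
#> RBC warm-up fit (shifted-exponential family)
#>   tau_mean    =   55.3 min  (R2 = 0.9999)
#>   tau_surface =   47.8 min  delta_surface = 0.116  (R2 = 0.9898)
#>   tau_core    =   63.9 min  delta_core    = 0.083  (R2 = 0.9965)
#>   t_spread = 17.6 min, theta_spread_max = 0.209, ratios 0.86 / 0.75
#>   alpha = 1.057e-08 /degC, Biot = 0.23
```

The fitted ordering τ_surface < τ_mean < τ_core and positive shifts emerge
from the diffusion physics; the PRF coefficient is recovered within 1 % of
the generator truth.

The numbered scripts under `analysis/` run the full study narrative
(calibration, simulation + extraction, model fits and cold-chain tables,
synthetic cohort statistics) and write their tables under `results/`.

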