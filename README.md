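# cdtime

Simulation and inference toolkit for a comparator-based dynamical model of
interval timing — for computational neuroscientists and psychophysicists who
want to simulate, perturb and recover the parameters of a subjective-time
gain model.

## The model

Subjective time runs at a time-dependent gain relative to objective time:

```
Δt_s = κ(t) · Δt,        τ_p_s(t) = κ(t) · τ_p
```

κ > 1 is dilation (time feels longer), κ < 1 compression. Deviations are
summarised by the relative deviation `D_r = κ − 1`, the absolute deviation
`D_a = τ_p_s − τ_p`, and the timing precision `P = 1 / |D_r|`. The brain's
regulatory loop pulls κ back to 1 through damped second-order dynamics

```
D_r'' = −a·D_r − b·D_r',       a, b > 0
```

— a restoring force proportional to the deviation plus a damping force that
keeps the return smooth (non-oscillatory when `b² ≥ 4a`). The total gain is
composed from cerebellar, basal-ganglia and cortical component gains,

```
κ = κ_BG^w_BG · κ_CTX^w_CTX · C(κ_CBL, κ_BG+CTX)
```

with duration-dependent weights (cerebellum dominates sub-second timing,
basal ganglia supra-second, cortex peaks in between; the CBL/BG weights
cross at ~1 s) and a cerebellar comparator `C` that pushes the composed
gain back toward 1 with strength `g ∈ [0, 1]`. Disorder regimes are encoded
as signed per-system presets (e.g. mania compresses, depression dilates,
schizophrenia and ASD jitter), and forward models turn a κ state into
synthetic interval-reproduction, temporal-bisection, tapping and EEG
spectral-peak observations, from which the estimators recover the
parameters.

## Worked example

```r
library(cdtime)

# a mildly dilated state relaxing back to veridical timing
p  <- dynamics_params(1, 2)                   # critically damped
tr <- solve_deviation_closed_form(p, 0.4, 0, seq(0, 10, 0.1))
tr
#> Gain trajectory: 101 samples on t = [0, 10] s
#>   mean kappa 1.0812, mean |D_r| 0.0812, final D_r 1.998e-04
#>   dynamics: a = 1, b = 2 (critical)

# a disorder scenario: major depression dilates supra-second timing
simulate_scenario(preset("major_depression"), spec = comparator_spec(0))
#> Scenario: preset 'major_depression', tau = 2 s, comparator g = 0
#>   damping: critical; mean kappa = 1.1844; mean |D_r| = 0.1844
#>   classified: dilated, precision low

# recover kappa from 100 synthetic reproduction trials at kappa = 0.8
set.seed(42)
r <- reproduce_interval(1, kappa_enc = 0.8, noise_cv = 0.05, n = 100)
fit_kappa_reproduction(r, 1, seed = 42)
#> Gain estimate: kappa = 0.8003 (95% CI 0.7921-0.8084, n = 100)

# recover (a, b) from the sampled deviation trajectory
fit_dynamics(tr$t, tr$d_r)
#> Restoring-dynamics fit
#>   a = 1, b = 2 (underdamped); D_r0 = 0.4, dD_r0 = -3.197e-13
#>   RSS = 1.366e-26, sigma = 1.187e-14, converged: TRUE
```

The first block shows the restoring law at work: an initial 8% dilation
(mean κ 1.08 over the window) decays to `D_r ≈ 2e-4` by 10 s. The scenario
summary classifies the depression preset as dilated with low precision
(mean κ 1.18 at a 2 s probe). The two fits recover the generating gain
(0.8003 vs 0.8) and the dynamics coefficients (exactly, on noiseless data;
the boundary regime label flips between critical and underdamped at
machine precision).

Reproducible pipelines are driven by a JSON/YAML config through `cdt_run()`
or the thin CLI at `inst/cli/cdt.R`:

```sh
Rscript inst/cli/cdt.R scenario --config cfg.json --out out/ --seed 5
```

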