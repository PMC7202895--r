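# aeropattern

Oxygen-driven aggregation and Turing-like pattern formation in dense
*Caenorhabditis elegans* populations.

When thousands of worms feed together, the bacteria they concentrate
deplete the oxygen in the surface liquid; low oxygen slows the worms, and
slow worms pile up — a motility-induced phase separation that produces
dots, stripes and hole patterns on the lawn. `aeropattern` implements the
minimal continuum model of this feedback and everything needed to study it
quantitatively:

* **Model core** — the parabolic motility law `V(O) = aO² + bO + c` with
  tumbling rate τ, the derived transport coefficients
  `D_W = V²/(2τ)` (dispersal) and `β = (V/2τ) dV/dO` (aerotaxis), and the
  uniform equilibrium `O_eq = O_am − k_c W_eq / f`.
* **Linear stability theory** — closed-form dispersion relation for the
  coupled worm/oxygen system, the instability criterion
  `W_eq β k_c > f D_W`, the unstable wavenumber band, the two critical
  densities bounding the (re-entrant) instability zone, and
  density × ambient-oxygen phase diagrams.
* **Simulator** — a conservative finite-volume integrator for
  `∂W/∂t = ∇·(D_W ∇W + β W ∇O)`,
  `∂O/∂t = D_O ∇²O + f(O_am − O) − k_c W`
  on a periodic 2-D grid (compiled core, exact mass conservation, CFL
  guard, seeded reproducible noise, JSON run manifests).
* **Pattern metrics** — deterministic dots/stripes/holes/uniform
  classification, radially averaged structure spectra with characteristic
  length, coarsening curves, and the swarm gradient decay length
  `λ = sqrt(D_b/f_b)`.
* **Calibration** — estimators that recover every model parameter
  (a, b, c, τ, f, k_c, D_O) from observations, with broom-style `tidy()` /
  `glance()` accessors.
* **Synthetic data** — seeded generators for motility assays, oxygen
  relaxation traces, run-and-tumble trajectories, labelled pattern
  fixtures and equilibrium datasets, so every estimator and metric is
  testable end to end without external data.

## Worked example

Where does a population of 60 worms/mm² under atmospheric oxygen sit in
the stability landscape, and what pattern does it actually form?

```r
library(aeropattern)

p <- model_params()          # calibrated defaults, SI units
equilibrium_oxygen(p, W_eq = 6e7)
#> # A tibble: 1 × 2
#>       W_eq  O_eq
#>      <dbl> <dbl>
#> 1 60000000 0.143

critical_densities(p)
#> # A tibble: 2 × 3
#>   root            W W_per_mm2
#>   <chr>       <dbl>     <dbl>
#> 1 W_lower 34778771.      34.8
#> 2 W_upper 89533279.      89.5

fastest_growing_mode(p, 6e7)
#> # A tibble: 1 × 4
#>   unstable   k_sq_max k_star growth_max
#>   <lgl>         <dbl>  <dbl>      <dbl>
#> 1 TRUE     414171676. 12277.      0.105
```

So 60 worms/mm² lies inside the instability zone (which spans ~35–90
worms/mm²): the uniform state's oxygen settles at 14.3%, perturbations
with wavenumbers up to `sqrt(4.1e8) ≈ 2.0e4` 1/m grow, and the fastest
mode (`k* ≈ 1.2e4` 1/m, i.e. a ~0.5 mm wavelength) doubles every
`log(2)/0.105 ≈ 6.6` s. Simulating 10 model-minutes from 1% noise
confirms the prediction:

```r
g  <- grid2d(N = 128, L = 0.02)   # 2 cm periodic box
tr <- run_simulation(p, g, W_eq = 6e7, t_end = 600, save_every = 600,
                     seed = 1)
classify_pattern(tr$states[[2]]$W)
#> [1] "dots"
structure_spectrum(tr$states[[2]]$W, g)
#> <structure_spectrum> k_peak = 1.32e+04 1/m, length = 0.0004762 m (reliable)
```

The emerged pattern length (0.48 mm) sits within a few percent of the
linear prediction `2π/k* ≈ 0.51 mm`. Sweeping the density upward through
the unstable interval (e.g. 20, 45, 70, 85 worms/mm²) yields the
sequence uniform → dots → stripes → holes; `autoplot(phase_diagram(...))`,
`plot_dispersion()` and `plot_field()` visualise the rest.

## Documentation

The methods vignette (`vignettes/oxygen-driven-patterns.Rmd`) describes
the model and its assumptions, the numerical scheme and its invariants,
the classification conventions, the calibration estimators, and the known
limitations of both the model and the synthetic data.
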