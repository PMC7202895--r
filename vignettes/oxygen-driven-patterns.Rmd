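---
title: "Modelling oxygen-driven aggregation and pattern formation in worm populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen-driven aggregation and pattern formation in worm populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

```{r setup}
library(aeropattern)
library(ggplot2)
```

## The model

Dense populations of *C. elegans* feeding on a bacterial lawn self-organise
into dots, stripes, labyrinths and hole patterns. The mechanism is
motility-induced phase separation mediated by oxygen: crowded worms (and the
bacteria they concentrate) deplete the oxygen in the surface liquid, low
oxygen slows the worms down, and slow worms accumulate further — a positive
feedback opposed by ordinary dispersal.

`aeropattern` implements the minimal continuum description of this feedback:
a Keller–Segel-type pair of fields on a periodic two-dimensional domain, the
worm areal density $W(\mathbf{x},t)$ and the oxygen fraction
$O(\mathbf{x},t)$,

$$\frac{\partial W}{\partial t} =
  \nabla\!\cdot\!\left[D_W(O)\,\nabla W\right] +
  \nabla\!\cdot\!\left[\beta(O)\,W\,\nabla O\right], \qquad
\frac{\partial O}{\partial t} =
  D_O \nabla^2 O + f\,(O_{am} - O) - k_c W .$$

Individual worms are run-and-tumble walkers: they crawl at an
oxygen-dependent speed $V(O)$ and reorient at rate $\tau$. Coarse-graining
that walk gives the two transport coefficients

$$D_W(O) = \frac{V(O)^2}{2\tau}, \qquad
  \beta(O) = \frac{V(O)}{2\tau}\,\frac{dV}{dO},$$

so a *single measurable behavioural curve* $V(O)$ controls both dispersal
and the aerotactic drift. We represent it as a parabola
$V(O) = aO^2 + bO + c$: fast at anoxia, nearly stationary near the preferred
oxygen level (the vertex, at $O \approx 0.105$ for the default
coefficients), and increasingly fast — and aggregation-prone — towards
atmospheric oxygen. The oxygen field gains from the air at penetration rate
$f$, diffuses along the wet surface with $D_O$, and is consumed in
proportion to the local worm density with coefficient $k_c$ (worm and
bacterial consumption are lumped together, since bacterial density tracks
worm density during aggregation; bacterial dynamics are otherwise outside
this package's scope).

### Parameters and units

Everything internal is SI: metres, seconds, worms/m², oxygen as a fraction
in $[0,1]$. User-facing tables and plots use worms/mm² and percent oxygen,
converted only at IO boundaries ([load_config()] accepts unit-suffixed keys
such as `D_O_cm2_per_s` or `W_eq_per_mm2`).

| parameter | meaning | default | units |
|---|---|---|---|
| $a, b, c$ | velocity parabola | $1.89\times10^{-2}$, $-3.98\times10^{-3}$, $2.25\times10^{-4}$ | m/s |
| $\tau$ | direction-change (tumbling) rate | 0.5 | 1/s |
| $D_O$ | surface oxygen diffusion | $2\times10^{-9}$ | m²/s |
| $f$ | air-to-surface oxygen penetration | 0.65 | 1/s |
| $k_c$ | consumption per unit worm density | $7.3\times10^{-10}$ | O₂-fraction·m²/(worm·s) |
| $O_{am}$ | ambient oxygen fraction | 0.21 | — |
| $L$ | periodic domain side | 0.02 | m |

A note on $k_c$: the consumption coefficient is often quoted as a bare rate,
which is dimensionally incomplete for a term $k_c W$ that must be an
oxygen-fraction rate. We fix its units as oxygen-fraction·m²/(worm·s) with
$W$ in worms/m². With the defaults above this places the instability zone
at roughly 35–85 worms/mm², inside the 1–90 worms/mm² range where uniform
populations are actually observed — the consistency check that motivated
the convention.

## Linear stability theory

A uniform density $W_{eq}$ forces the oxygen to
$O_{eq} = O_{am} - k_c W_{eq}/f$ (penetration balancing consumption;
`equilibrium_oxygen()`). Linearising about $(W_{eq}, O_{eq})$ and inserting
a perturbation $\propto \sin(kx)$ gives a $2\times2$ system
(`jacobian_at_k()`) whose eigenvalues `dispersion_relation()` returns in
closed form. The uniform state is unstable exactly when

$$W_{eq}\,\beta\,k_c \;>\; f\,D_W
\quad\Longleftrightarrow\quad
W_{eq}\,k_c\,\frac{dV}{dO} \;>\; f\,V
\qquad \text{(both sides at } O_{eq}\text{)},$$

i.e. when density and aerotactic response together beat dispersal
(`instability_criterion()`). The unstable wavenumbers form a band
$0 < k^2 < (W_{eq}\beta k_c/D_W - f)/D_O$ (`unstable_band()`), with the
fastest-growing mode located by a log-grid scan plus golden-section
refinement (`fastest_growing_mode()`; 512 scan points by default, ties
broken toward smaller $k$).

An important subtlety: the transport coefficients in these formulas are
evaluated at the *equilibrium* oxygen $O_{eq}$, not at ambient. The
derivation linearises around the equilibrium state, so this is the only
internally consistent choice, and it is what produces re-entrance: as
$W_{eq}$ grows, $O_{eq}$ slides down the velocity curve toward the vertex
where $\beta \to 0$, so very dense populations are stable again. At 21%
ambient oxygen the two critical densities bracket the patterned zone:

```{r crit}
p <- model_params()
critical_densities(p)
```

`critical_densities()` locates these roots by bisection (relative
tolerance $10^{-6}$ in $W$, bracket scan over 4096 points of the feasible
range); `phase_diagram()` tabulates the verdict over a density ×
ambient-oxygen grid, labelling infeasible cells (where consumption would
exceed supply) rather than erroring.

```{r disp, fig.height = 3.5}
plot_dispersion(p, W_eq = c(2e7, 4.5e7, 7e7) )
```

## The simulator

Cross-diffusion systems of this kind are often solved with general-purpose
finite-element software; this package instead implements an explicit
finite-volume scheme designed around two invariants we test exactly:

* **Conservative flux form.** Worm fluxes
  $D_W(O)\nabla W + \beta(O) W \nabla O$ are evaluated at cell faces with
  arithmetically averaged $O$ (and $W$ for the advective weight), and every
  face contributes equal and opposite amounts to its two cells, so total
  worm mass telescopes exactly (drift $<10^{-8}$ over $10^4$ steps is an
  acceptance property; in practice it is at rounding level).
* **Stability bound.** Explicit Euler with
  $dt \le 0.9\,dx^2 / (4\max(D_W, D_O))$, the worm diffusivity maximised
  over the reachable oxygen range, and $dt \le 0.1/f$ (`cfl_dt()`). A
  divergence detector aborts with a CFL diagnostic if $|W|$ exceeds
  $10^6\times$ its initial mean.

Positivity is our closure, not the continuum model's: the continuum
equations do not forbid negative oxygen under strong consumption, so after
each step $W$ is clamped at zero with the clamped mass redistributed
proportionally, and $O$ is clamped to $[0, O_{am}]$; every clamp event is
counted and logged in the run manifest.

Initial conditions follow the randomised-uniform convention: $W =
W_{eq}(1 + \varepsilon\,\eta)$ with $\eta$ i.i.d. uniform on $[-1,1]$,
mean-removed so the sample mean is exact, and $\varepsilon = 0.01$ by
default (the noise amplitude is not a sharply constrained quantity; 1% is
small enough to stay in the linear regime for a few minutes of model time,
large enough to seed every lattice mode). The PRNG is the Mersenne–Twister,
seeded explicitly and recorded in the manifest.

### Fidelity to the dispersion relation

`initialize_mode()` seeds a single harmonic along the slow eigenvector of
the linearised system; measuring the modal amplitude over 30 s of model
time reproduces the closed-form growth/decay rate. The package's tests run
this at $N = 256$ on a 1 cm domain for harmonics 5 and 10 (in-band,
growing) and 20 (beyond the band edge, decaying), where all three measured
rates agree with theory within 5% (the in-band ones within 0.3%; the
decaying mode's error is spatial discretisation, $k\,dx \approx 0.5$, and
halves again at $N = 512$).

### Problem sizes

The shipped tests and acceptance checks use $N = 128$ over $L = 2$ cm for
pattern phenomenology (10 and 30 model-minutes; $dt \approx 0.1$ s, about
6000–18000 steps, a few seconds per run with the compiled core), $N = 256$
for modal fidelity and diffusion calibration, and $N = 32$ grids for
conservation/fixed-point properties. These sizes resolve the unstable band
(shortest unstable wavelength ≈ 0.3 mm ≈ 2 cells at $N = 128$ only at the
extreme edge; the *selected* wavelength $2\pi/k_\ast \approx 0.5$ mm is
comfortably resolved) while keeping a full density sweep to a couple of
minutes.

## Pattern morphology

The dots → stripes → holes taxonomy of these patterns is conventionally
assigned by eye. `classify_pattern()` fixes a deterministic closure,
with every threshold exposed as an argument and frozen in the tests:

1. coefficient of variation $< 0.05$ → `uniform`;
2. otherwise binarise at the field mean; let $\phi$ be the high-phase area
   fraction; find periodic 4-connected components of both phases; call a
   component *compact* when perimeter²/area $< 30$ in cell units
   (a digitised disc scores ≈ 20, bands score $\sim 4\,\ell/w \gg 30$);
3. $\phi < 0.4$ with ≥ 3 compact high-phase components → `dots`;
   $\phi > 0.6$ with ≥ 3 compact low-phase components → `holes`;
   otherwise `stripes`.

These thresholds are conventions of this package, not measured quantities;
the simulated
density sweep is insensitive to moderate changes (the measured $\phi$ moves
from 0.17 to 0.62 across the unstable interval, crossing the thresholds
far from the sweep's labelled densities).

`structure_spectrum()` takes the radially averaged 2-D power spectrum in
bins of the domain fundamental $2\pi/L$ (zero mode excluded) and reports
the characteristic length $2\pi/k_{peak}$. A peak is trusted only when it
is (i) at least twice the median bin power and (ii) statistically
incompatible with a flat spectrum: each bin averages $n$ periodogram
ordinates, so under white noise its relative fluctuation is
$\sim 1/\sqrt{n}$, and we require the z-score
$(P_{peak}/P_{med} - 1)\sqrt{n_{peak}} \ge 5$. The simple 2×-median rule
alone is not enough — the maxima of a genuinely flat spectrum land in the
sparse low-$k$ bins and reach 2.7× the median in a quarter of white-noise
realisations, while true pattern spectra (which are broadband, with sharp
domain walls) only peak at ~4× the median; the z-score separates the two
cleanly.

`coarsening_curve()` applies the spectrum per frame and reports whether the
patterned segment of the series is non-decreasing within tolerance. A
caveat worth stating plainly: because the dispersion relation selects a
finite wavelength, domain growth in this model *arrests*. The
characteristic length grows from the fastest-growing-mode scale
(≈ 0.43 mm at the defaults) to the saturated selected scale
(≈ 0.48–0.50 mm) within the first few model-minutes and then freezes;
the coarsening test therefore samples snapshots every 60 s so the first
patterned frame precedes saturation. Long-time merging into a single swarm
as observed on real lawns involves bacterial depletion, which is outside
this model. `gradient_decay_length()` implements the swarm-width relation
$\lambda = \sqrt{D_b/f_b}$ for a bacterial gradient maintained by diffusion
against consumption.

## Calibration estimators

Each printed parameter is recoverable from data this package can also
synthesise, and each estimator is validated against an independent route:

* `fit_velocity_curve()` — OLS parabola through (O, V) assays; exact on
  noiseless samples, coefficient coverage checked by Monte-Carlo.
* `estimate_penetration_rate()` — log-linear fit of the oxygen deficit of a
  worm-free relaxation trace. The estimator truncates the trace at the
  first crossing below five times the noise floor (estimated from the final
  10% of the trace): beyond that point the log-deficit is noise, and
  including it biases the slope badly (a censored tail at 1 mHz noise
  produced a 50% bias in early experiments — the truncation is load-bearing).
* `estimate_consumption_rate()` — through-origin regression of
  $f(O_{am} - O_{eq})$ on $W$; the test data come from time-integrating the
  uniform oxygen ODE (`make_equilibrium_dataset()`, via `deSolve`), not the
  closed form, so the route is genuinely independent.
* `estimate_turn_rate()` — ensemble MSD of run-and-tumble trajectories;
  $\hat D$ from the long-time slope (MSD $= 4Dt$), inverted through
  $\tau = V^2/(2D)$. Default window $[5/\hat\tau_0, T/2]$ with
  $\hat\tau_0$ from a first pass, so the ballistic transient
  ($t \lesssim 1/\tau$) is excluded; ballistic inputs are flagged
  superdiffusive rather than fitted.
* `estimate_oxygen_diffusion()` — per-axis variance of a spreading bump,
  $\sigma^2(t) = \sigma^2(0) + 2Dt$. For the discrete Laplacian this
  relation is *exact* (the lattice second moment grows at exactly $2D$ per
  unit time), so recovery is limited only by the fit, and bumps wider than
  the wrap-safe limit are rejected.

The turn generator draws turns per step with probability
$1 - e^{-\tau\,dt}$ (the exact Poisson probability of at least one event;
with uniform tumbles the end-of-step direction distribution is exact and
the position error is $O(dt)$), with $dt \le 0.1/\tau$ enforced.

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the estimators assume —
exact kinematics plus declared additive Gaussian noise, seeded and
reproducible. They do not emulate image-derived measurement artifacts
(segmentation error, uneven illumination), worm-body-scale granularity,
behavioural state switching, or bacterial depletion over long times. A
passing calibration suite therefore demonstrates estimator correctness
under the declared noise model, not robustness to every failure mode of
real assays.

## Design choices and limitations

* **Analysis shape.** The package is organised tidyverse-style — data
  frames in, tibbles out, `tidy()`/`glance()` on fits, `autoplot()` on
  result classes — because every interface object here (assay tables,
  dispersion curves, phase diagrams, metric series) is naturally tabular.
  Field states are plain numeric matrices inside a light S3 record.
* **Sweep densities.** The scaled-down density sweep uses 20, 45, 70 and
  85 worms/mm² at 21% oxygen: one stable density plus three spread across
  the unstable interval (35–85), matching where theory places dots
  (just above onset, low $\phi$), stripes ($\phi \approx 0.5$) and holes
  (near the upper boundary).
* **No amplitude equations.** Pattern type is decided by simulation plus
  classification; the package deliberately contains no weakly nonlinear
  theory.
* **No bacterial field.** Bacterial consumption dynamics, biofilm effects
  and swarm translocation mechanics are out of scope; only the gradient
  decay-length relation is provided.
* **Degenerate inputs.** Constant fields are flagged `no peak` rather than
  assigned a length; stable runs yield `uniform` frames and an `NA`
  coarsening verdict; infeasible equilibria error early with the feasible
  bound in the message.
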