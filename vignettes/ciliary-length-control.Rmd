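---
title: "Flux-balance modeling of motor recycling and ciliary length control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-balance modeling of motor recycling and ciliary length control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaflux)
```

## The model

Cilia and flagella are built and maintained by intraflagellar transport
(IFT): kinesin-II motors carry trains of structural material from the
ciliary base to the tip, deposit their cargo, and — in *Chlamydomonas* —
return to the base by passive diffusion rather than active retrograde
transport. `ciliaflux` implements a deterministic flux-balance model of
this cycle for a single cilium, built around one structural assumption:
the pool of `N` motors is conserved and partitioned, at any length `L`,
into three states,

* ballistic (walking tipward): `N_ballistic = J * L / v`,
* diffusive (returning): `N_diffusive = J * L^2 / (2 * D)`,
* free at the base: `N_free = J / K`,

where `v` is the anterograde speed, `D` the diffusion constant, and the
injection flux is proportional to the free pool, `J = K * N_free`.
Because transport across the cilium takes seconds while regeneration
takes hours, the partition is in quasi-steady state and the flux balance
closes to

```
J(v, L) = N / (1/K + L/v + L^2/(2D))
```

so the injection rate falls with length — the empirical 1/L-like scaling
— without any length sensor: a longer cilium simply sequesters more of
the motor pool in transit, starving the base.

Three rate laws convert this flux into length dynamics:

1. **Motor-limited** (`"case1"`): `dL/dt = delta * J - d`; each arriving
   motor adds `delta` micrometres, disassembly is constant.
2. **Tubulin-limited** (`"case2"`): `dL/dt = alpha * J * (T - L) - d`;
   growth also slows as the tubulin pool `T` (expressed as length) is
   consumed.
3. **Length-dependent disassembly** (`"case3"`):
   `dL/dt = delta * J - d - d1 * J * L / D`; a recycled depolymerizer
   adds a disassembly term growing with length.

Setting each law to zero yields a quadratic `L^2 + 2 b L + c = 0` whose
positive root is the steady-state length; `lss_closed_form()` returns it
together with an existence flag (the negative-discriminant or
negative-root region is a legitimate "no growth" regime that the sweeps
paint, not an error).

## Parameters, units, defaults

Lengths are in micrometres, times in seconds, motors are dimensionless
counts. `K` carries units 1/s so that `J = K * N_free` is a flux; `1/K`
is the reinjection delay at the base. The reference preset
(`preset_params()`) is `N = 100`, `K = 1/s`, `D = 2.5 um^2/s`,
`delta = 1.5e-3 um`, `d = 0.004 um/s`, with wild-type speed
`v = 2.3 um/s` and the slow chimeric speed `0.80 um/s`; case 2 adds
`T = 30 um`, `alpha = 0.8e-4`; case 3 uses `d = 0.002 um/s` and
`d1 = 0.1 * d`. Two unit conventions are deliberate: `d1` is stored as
the plain number `0.1 * d` (the dimensional bookkeeping of the case-3
cross term is ambiguous, so it is used exactly as specified), and
`alpha` is treated as dimensionless per motor. The diffusive residence
time uses the mean 1-D transit `L^2/(2D)`, matching the `L^2/(2D)` term
of the flux balance.

```{r}
p <- preset_params("case1")
lss_closed_form(p, "case1")$L_ss                     # 12.47 um
lss_closed_form(preset_params("case1", v = 0.8), "case1")$L_ss  # 10.74 um
```

The headline prediction is the nonlinear speed-to-length scaling: a
~3-fold slower motor shortens the cilium by only ~15%, and a much faster
motor saturates at `sqrt(-c)`:

```{r}
fold_change_curve(p, "case1", c(1/3, 1, 10))
```

The proportional baseline (`baseline_linear_lss()`, `L_ss = A*v/d`)
predicts a 3-fold reduction instead — that contrast is the reason the
recycling model exists.

## Numerical choices

* **Integrator.** The length ODE is one-dimensional and non-stiff, so
  `simulate_regeneration()` uses an adaptive Dormand-Prince 5(4) pair
  (relative tolerance 1e-8, absolute 1e-10) written in-package — no ODE
  solver package is available in the target environment. The test suite
  cross-checks it against a fixed-step RK4 oracle at `dt = 0.01 s`
  (< 1e-4 um disagreement on the presets) and against the closed-form
  steady states over hundreds of random parameter draws.
* **Clamping.** When disassembly dominates an empty cilium
  (`d > delta*K*N` at `L = 0`), the length is held at zero rather than
  integrated negative.
* **Degenerate inputs.** `L = 0` is fully supported (`J = K*N`); the
  tubulin-limited law rejects `L > T` rather than extrapolating a
  negative tubulin pool.
* **Horizon.** The default `t_end` of 3 h is past 99% convergence for
  the presets; for arbitrary parameters `suggest_t_end()` combines a
  growth ramp with fifteen relaxation times of the linearized dynamics
  at `L_ss`. Convergence is always verified against the closed form
  (the `converged` attribute), never assumed.
* **Growth time.** "Growth time" is not defined quantitatively in the
  source material; the package uses time to 95% of `L_ss`, linearly
  interpolated between output samples.
* **Elasticities.** `limitation_regime()` labels growth
  diffusion-limited or motor-limited by comparing log-log sensitivities
  of `L_ss` to `D` and `N`, central differences with a 1% relative step
  (configurable).

## Phase-space sweeps

`phase_space()` evaluates steady states (and optionally 95% growth
times) over a grid of motor numbers and diffusion constants at a fast
and a slow speed. The defaults — eight log-spaced `N` values in
50–400 and ten `D` values in 1–10 um^2/s — are a physiological window
around the reference point; the source material does not print its sweep
ranges, so these are package choices and fully configurable. Across this
window the slow/fast length ratio is always below 1 in all three cases
(the robustness result). One honest caveat: the ratio is not bounded
below by 0.7 everywhere — at the most diffusion-limited corner of the
default case-1 grid (`N = 50`, `D = 10`) it reaches 0.67, so "mild
reduction" should be read qualitatively, not as a universal 30% bound.

## What the synthetic data emulate — and what they do not

`generate_regen()` emulates fixed-timepoint regeneration assays: per
timepoint, `n_cells` (default 50) lengths equal to the deterministic
model curve plus additive Gaussian measurement noise, truncated at zero.
The default SD of 1.3 um is taken from the spread of reported
steady-state length distributions (e.g. 12.6 ± 1.3 um over 50 cells);
the default sampling grid, 0–120 min every 10 min, is a package choice
(the experimental grid is not printed). Truncation at zero is used
rather than resampling; at the default SD the induced bias is visible
only at the earliest timepoints where the true length is near zero.
`generate_injection()` emulates fluorescence-based injection-rate
measurements: the model flux times an unknown gain (arbitrary units per
motor/s) with multiplicative lognormal noise of mean exactly 1 and CV
0.15 by default, consistent with reported injection-rate spreads.

These generators reproduce the *statistical structure* of the
measurements, not their biology: cells are independent and identically
distributed around the deterministic curve, with no cell-to-cell
parameter variability, no correlated measurement drift, and no
stochasticity in IFT injection itself. A green recovery test therefore
establishes that the pipeline is self-consistent and statistically
efficient at realistic noise, not that the model is identified from any
particular real dataset.

## Parameter recovery and identifiability

From length-vs-time data alone, `N`, `delta` and `K` are not separately
identifiable — only the composites `a = delta*N`, `b = 1/K` enter the
motor-limited forward model `dL/dt = a/(b + L/v + L^2/(2D)) - d`.
`fit_regen()` therefore exposes exactly `(a, b, d)` and refuses requests
for the separate parameters; `v` and `D` are supplied as known, mirroring
their independent experimental measurement. The objective is squared
error on per-timepoint *means* (matching the mean ± SD reporting
convention), minimized by Nelder-Mead on log-parameters from 10 restarts
drawn log-uniform within a factor of 10 of plausible centers, then
polished with a quasi-Newton pass; proposals that make the ODE
transiently too stiff for the explicit integrator are scored as hopeless
rather than fatal. At zero noise the truth is recovered to well under 1%;
at the realistic noise level, `a` and `d` are recovered with a median
relative error below 10% while `b` stays poorly determined — its
sub-second delay is simply invisible at 10-minute sampling, and the fit
is honest about that rather than constraining it.

Fitting is implemented for the motor-limited case only: the extra
parameters of cases 2–3 are not identifiable from length-only synthetic
data, and no data exist that would constrain them.

## Known limitations

* No spatial PDE for the diffusing motor profile; the quasi-steady
  closure stands in for it by construction.
* No stochastic (discrete-motor) injection; the model is deterministic
  throughout.
* Single cilium only: no shared-pool biflagellar dynamics or severing
  experiments.
* The model predicts near-identical injection rates for wild-type and
  slow motors at their respective steady states; observed differences
  there are outside what this recycling mechanism can express.
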