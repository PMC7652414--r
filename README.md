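# ciliaflux

Deterministic flux-balance modeling of intraflagellar transport (IFT)
and ciliary length control by kinesin-II recycling.

## The problem

Cilia reach a well-defined steady-state length, and the IFT injection
rate falls as the cilium grows — yet a kinesin-II motor made ~3-fold
slower shortens *Chlamydomonas* cilia by only ~15%, where a model in
which assembly scales with motor speed predicts a 3-fold reduction.
`ciliaflux` implements the model that resolves this: a conserved pool of
N motors walks to the tip at speed v, returns by diffusion with constant
D, and is reinjected from the basal pool at rate K, so the injection
flux obeys

    J(v, L) = N / (1/K + L/v + L²/(2D))

and the motor pool partitions into N_ballistic = J·L/v,
N_diffusive = J·L²/(2D) and N_free = J/K. A longer cilium sequesters
more motors in transit, starving the base — injection falls with length
without any length sensor. Three length dynamics close the model:

| case | rate law | steady state |
|---|---|---|
| motor-limited | dL/dt = δJ − d | positive root of L² + 2(D/v)L + 2D(1/K − Nδ/d) = 0 |
| tubulin-limited | dL/dt = αJ(T − L) − d | analogous quadratic |
| length-dependent disassembly | dL/dt = δJ − d − d₁JL/D | analogous quadratic |

Because the diffusive return time grows as L², the steady state depends
only weakly on v: with the reference parameters (N = 100, K = 1/s,
D = 2.5 µm²/s, δ = 1.5×10⁻³ µm, d = 0.004 µm/s) the model gives
L_ss = 12.47 µm at v = 2.3 µm/s and 10.74 µm at v = 0.80 µm/s.

The package is for modelers and quantitative cell biologists who want to
explore this class of organelle-size-control models: closed-form steady
states with existence flags, ODE regeneration kinetics, motor-pool
partitions, (N, D) phase-space sweeps, synthetic measurement data with
realistic noise, and parameter recovery respecting the model's
identifiability structure.

## Worked example

```r
library(ciliaflux)
p <- preset_params("case1")          # reference motor-limited parameters

lss_closed_form(p, "case1")$L_ss
#> [1] 12.46596

fold_change_curve(p, "case1", c(1/3, 1, 10))
#>            case    v_ratio     L_ss fold_change
#> 1 motor_limited  0.3333333 10.63637   0.8532333
#> 2 motor_limited  1.0000000 12.46596   1.0000000
#> 3 motor_limited 10.0000000 13.40100   1.0750075
```

A third of the motor speed costs only ~15% of the length
(fold change 0.853), and a 10× faster motor gains just 7.5% —
the saturation bound here is √(2D(Nδ/d − 1/K)) = 13.51 µm. At the
steady state the partition shows why: most motors are diffusing back,

```r
motor_partition(p, 12.46596)
#>          L n_ballistic n_diffusive   n_free
#> 1 12.46596    14.45328    82.88005 2.666667

residence_times(12, 2.3, 2)   # anterograde vs diffusive return, seconds
#>   t_ballistic t_diffusive  t_total
#> 1    5.217391          36 41.21739
```

Regeneration from deflagellation converges to the closed form,

```r
traj <- simulate_regeneration(p, "case1", t_end = 3 * 3600, dt_out = 10)
traj
#> Ciliary regeneration trajectory (motor_limited)
#>   1081 samples over 10800 s; L: 0.000 -> 12.459 um
#>   closed-form L_ss = 12.466 um; converged: TRUE
```

and the synthetic-data + inference loop recovers the identifiable
composites a = δN, b = 1/K and d from a simulated 50-cells-per-timepoint
regeneration assay with 1.3 µm measurement noise:

```r
ds  <- generate_regen(p, "case1", seed = 1)
fit_regen(ds, v_known = 2.3, D_known = 2.5)
#> Regeneration fit (least squares on timepoint means)
#>   a = delta*N : 0.15508 um/s
#>   b = 1/K     : 1.0241 s
#>   d           : 0.0041743 um/s
#>   SSR 0.4048; converged: TRUE (10 restarts)
```

(truth: a = 0.15, b = 1, d = 0.004). Phase-space sweeps over (N, D) and
the pipeline commands (`cmd_steady_state()`, `cmd_simulate()`,
`cmd_sweep()`, `cmd_synthesize_and_fit()`, plus the
`inst/cli/ciliaflux.R` dispatcher) are described in the methods
vignette, `vignettes/ciliary-length-control.Rmd`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the closed-form steady-state lengths at the wild-type and slow
motor speeds and the endpoint of an ODE regeneration from zero length,
and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
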