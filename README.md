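# bgctdyn

Bifurcation analysis and potential landscapes for a firing-rate model of
the cortex–basal ganglia–thalamus (BGCT) loop under low dopamine.

## The problem

Beta-band (13–30 Hz) oscillation of cortical activity is a core
dynamical signature of Parkinson's disease, and is shaped by the balance
between the striatum's *direct* pathway (D1 neurons → GPi, weight
`T42`) and *indirect* pathway (D2 neurons → GPe, weight `T53`).
`bgctdyn` implements a seven-population rate model of this loop —
cortex, striatal D1/D2, GPi, GPe, thalamus, STN — in which each
population obeys

    C_i dx_i/dt = I_i − x_i/R_i + Σ_j ±T_ij · H(x_j)  (± D_input),

with Hill response `H(x) = x^n/(s^n + x^n)` (`s = 2`, `n = 2`), membrane
time constant `R·C ≈ 6 ms`, and dopamine `D_input` exciting D1 and
inhibiting D2.  The package is for modellers who want to reproduce and
extend the loop's full dynamical repertoire: as `T42` and `T53` vary
over `[0, 7]` the cortex shows one, two or three stable steady states,
one or two stable limit cycles, and their coexistence — organized by
fold and Hopf bifurcations, cusp points, and a 12-region map of the
`(T42, T53)` plane.

## What the package provides

* `bgct_params()` — the full parameter set (published typical values).
* `bgct_drift()` / `bgct_jacobian()` — compiled vector field and exact
  Jacobian.
* `find_equilibria()` — multistart damped-Newton enumeration of
  equilibria with eigenvalue stability labels.
* `integrate_bgct()`, `detect_attractor()`, `attractor_census()` —
  simulation-based census of stable steady states and limit cycles
  (regime tags like `"2SS+1LC"`), with period, frequency and beta-band
  classification.
* `trace_branch()` — codimension-1 pseudo-arclength continuation with
  fold/Hopf detection and stable-cycle envelopes.
* `trace_codim2_curves()` / `region_map()` — fold and Hopf curves in a
  two-parameter plane, cusp points, and the region decomposition with
  per-region censuses.
* `noise_spec()`, `langevin_simulate()`, `estimate_pss()`,
  `potential_landscape()` — seeded Euler–Maruyama ensembles and the
  potential landscape `U = −ln(Pss)` on the `(x1, x2)` plane, with
  minima and limit-cycle ring detection.
* `load_config()`, `write_manifest()`, `generate_fixtures()` and a thin
  CLI (`inst/scripts/bgct-cli.R`) for reproducible pipeline runs.

## Worked example

Mid-way between the two Hopf points of the indirect-pathway slice
`T53 = 4`, the loop's only attractor is a beta-band limit cycle:

```r
library(bgctdyn)
p <- bgct_params(T42 = 5, T53 = 4)
attractor_census(p)
#> Attractor census: 0SS+1LC
#>   limit cycle: period 66.92 ms (14.9 Hz, beta band), x1 in [0.2384, 1.887]
```

The census tag `0SS+1LC` says no stable steady state coexists with one
stable limit cycle; the cycle's period (66.9 ms) corresponds to 14.9 Hz,
inside the 13–30 Hz beta band, and the envelope `[0.24, 1.89]` is the
swing of cortical activity over one cycle.  The bistable window of the
direct-pathway slice looks like this instead:

```r
find_equilibria(bgct_params(T42 = 2, T53 = 0))
#> Equilibria: 3 found ( 2 stable )
#>         x1   max_re stability residual
#> 1 0.169682 -0.07911    stable  9.9e-12
#> 2 0.559614  0.03908  unstable  1.9e-12
#> 3 1.945970 -0.07097    stable  5.2e-15
```

— two stable cortical firing levels (low 0.17, high 1.95) separated by a
saddle, i.e. classical bistability; `max_re` is the largest eigenvalue
real part (1/ms) at each equilibrium.

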