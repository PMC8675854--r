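---
title: "Bifurcations and potential landscapes of a basal ganglia-thalamocortical loop model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifurcations and potential landscapes of a basal ganglia-thalamocortical loop model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bgctdyn` analyses a firing-rate model of the cortex–basal
ganglia–thalamus (BGCT) loop with seven interacting populations: cortex
(1), striatal medium spiny neurons with D1 (2) and D2 (3) receptors, the
internal (4, GPi) and external (5, GPe) globus pallidus, thalamus (6) and
the subthalamic nucleus (7, STN).  Each population carries one activity
variable $x_i$ obeying

$$C_i \frac{dx_i}{dt} = I_i - \frac{x_i}{R_i}
  + \sum_j \pm\, T_{ij}\, H(x_j) \;(\pm D_{\mathrm{input}}),$$

where $H(x) = x^n/(s^n + x^n)$ is a Hill response with coefficient
$s = 2$ and index $n = 2$, $T_{ij} \ge 0$ is the connection weight from
population $j$ to $i$ (excitatory `+`, inhibitory `-`), $C_i R_i$ is the
membrane time constant (about 6 ms with the default $C = 3.60$,
$R = 1.67$), and the dopamine level $D_{\mathrm{input}}$ excites the D1
population and inhibits the D2 population.  Time is in milliseconds
throughout; a limit cycle of period $T$ ms oscillates at $1000/T$ Hz.

The two striatal output weights are the scientific knobs: $T_{42}$
(striatum D1 → GPi, the *direct* pathway) and $T_{53}$ (striatum D2 →
GPe, the *indirect* pathway).  Under low dopamine their balance shifts,
and the loop can move from steady firing into multistability or beta-band
(13–30 Hz) oscillation.  All other weights and inputs default to the
published typical values and are rarely changed.

Two modelling conventions deserve note:

* The tabled values give $RC = 6.012$ ms while the nominal time constant
  is quoted as 6 ms.  The package uses the tabled $C$ and $R$ verbatim in
  every computation; "$\tau \approx 6$ ms" is documentation only.
* The equations do not clamp activity at zero, and with an even Hill
  index the response is defined (and even) for $x < 0$; the deterministic
  field is therefore left unclamped, exactly as printed.  An optional
  reflecting floor at 0 exists only in the stochastic integrator and is
  off by default.
* `bgct_params()` must choose *some* default for $T_{42}$ and $T_{53}$,
  which the typical-value table does not fix.  Both default to 1, a
  monostable operating point; every analysis sets them explicitly.

## Equilibria and stability

`find_equilibria()` runs a damped Newton iteration (analytic Jacobian,
residual-decreasing backtracking) from a deterministic Halton grid of
2000 starts spanning `search_box = c(-1, 10)` per variable, deduplicates
roots at $10^{-5}$ max-abs distance, and classifies stability from the
Jacobian spectrum with a margin of $10^{-8}$/ms on the real parts
(eigenvalues closer to the axis flag the point as bifurcation-adjacent).
The box only *seeds* the starts: converged roots outside it are kept,
because at strong direct-pathway inhibition the GPi equilibrium
coordinate falls below $-1$.  A Halton sequence rather than a seeded
pseudo-random cloud makes the result a pure function of its arguments.

The test suite checks completeness against an independent enumeration
that exploits the loop's wiring: fixing thalamic activity $x_6$
determines $x_1, x_2, x_3$ in closed form, the GPe–STN subsystem reduces
to a scalar contraction (unique inner fixed point by bisection), and all
equilibria appear as roots of one continuous scalar residual in $x_6$.

## Attractor census

`attractor_census()` integrates the model (stiff-capable `lsoda` with
compiled right-hand side and analytic Jacobian, dense output every
0.1 ms) from a deterministic set of initial conditions, classifies each
trajectory with `detect_attractor()`, and reports the canonical regime
tag `kSS+mLC`.  Attractor detection discards the first half of the
trajectory; if every variable's remaining peak-to-peak amplitude is below
`osc_threshold = 1e-3` the endpoint is Newton-polished into an
equilibrium, otherwise the period is the mean of the last inter-peak
intervals of $x_1$ (peak times refined by quadratic interpolation, so
period resolution is finer than the reporting step), accepted only when
their coefficient of variation is below 2%.  If single intervals
alternate — two unequal maxima per period — paired intervals are tried
before declaring the trajectory undecided.  Undecided trajectories are
retried once at twice the horizon, as are trajectories whose endpoint
polishes onto an *unstable* equilibrium (the signature of slow escape
close to a Hopf curve); censuses that still contain unresolved runs are
flagged non-exhaustive.

Two cycles are the same attractor only when their periods agree within
2% *and* their mean states within 0.05 — deliberately strict, because the
strong-indirect-pathway corner of the plane holds two coexisting cycles
that must not merge.  The default initial-condition grid (64 Halton box
points plus paired perturbations of every equilibrium along its leading
eigenvector) is what `estimate_pss()` also uses; the cheaper
`ic_strategy = "targeted"` variant integrates only from perturbed
unstable equilibria.  Every limit cycle in this model is born in a
supercritical Hopf bifurcation and therefore coexists with an unstable
equilibrium, so the targeted strategy finds the same attractors; the
suite cross-checks it against the full grid at randomly drawn parameter
points.

## Bifurcation continuation

`trace_branch()` performs pseudo-arclength continuation of equilibrium
branches in one weight (initial step 0.01, adaptive in
$[10^{-5}, 0.1]$, Newton corrector tolerance $10^{-10}$), seeded from
root searches at five values across the range.  Folds are detected as
turning points of the branch in the scan parameter and refined by Newton
iteration on $\{f = 0,\ \det J = 0\}$; Hopf points as sign changes of the
real part of the *leading complex pair* (tracked directly — cheaper at
dimension 7 than a bialternate determinant, which the tests use as a
cross-check through an independent eigen-decomposition) and refined on
$\{f = 0,\ \mathrm{Re}\,\lambda = 0\}$.  Eigenvalue pairs with
$|\mathrm{Im}\,\lambda| < 10^{-4}$ at a real-part zero are classified
fold-adjacent, not Hopf.  Stable-cycle envelopes along a scan come from
simulation at a sub-grid of parameter values, seeded from the branch
states themselves.

`trace_codim2_curves()` continues every fold and Hopf point found on
boundary slices through the corresponding extended system in
$(x, p_1, p_2)$ — $\{f=0, \det J=0\}$ or
$\{f=0, \mathrm{Re}\,\lambda_{\text{pair}}=0\}$ — with the same
predictor–corrector machinery (the test-function row of the Jacobian is
finite-differenced; the drift rows are analytic).  Hopf curves stop where
the pair's imaginary part collapses below $10^{-4}$; such endpoints are
bridged to the nearest fold-curve point before region decomposition, so
the degenerate gap cannot leak between regions.  Cusp points are emitted
where a fold curve's in-plane direction of travel reverses — the
turning point of the curve in the plane, where the two fold branches
meet.

`region_map()` combines both: the traced curves are rasterized on a fine
grid (8 cells per lattice step), the complement is flood-filled into
faces (4-connectivity), and every face becomes one region.  A census
lattice (default 71 × 71) provides the tags; faces too thin to contain a
lattice point are censused at their deepest interior cell, which is the
refinement pass that keeps narrow regions alive.  Two faces separated by
a bifurcation curve count as different regions even if they carry the
same tag, matching how the underlying diagrams delimit regions by
codimension-1 curves.  A face must be at least as large as one lattice
cell to count as a region: sub-lattice faces (for instance a cusp wedge
clipped to a tiny corner by the window edge) are below the map's
resolving power and are excluded from `region_count`.  Hopf curves are
traced only over their *active* part — where the crossing pair belongs
to an otherwise non-repelling equilibrium — because a Hopf on a saddle
changes no attractor and bounds no regime.

For the GPi-input plane $(T_{45}, T_{47})$ the published analysis never
states the fixed values of $T_{42}$ and $T_{53}$ (nor its per-region
representative points); `region_map()` therefore requires them
explicitly.  The package's tests use $(T_{42}, T_{53}) = (5, 4)$, an
oscillation-prone operating point at which that plane exhibits all four
of its stable dynamics (one or two steady states, a lone cycle, and
steady-state/cycle coexistence); the per-regime representative points
used by the fixture generator are documented in
`regime_representatives()`.

## The potential landscape

`estimate_pss()` adds additive Gaussian white noise to every equation
(Euler–Maruyama, $x \leftarrow x + f\,dt + \sqrt{2 D\, dt}\,\eta$,
default $dt = 0.01$ ms, $D = 10^{-6}$) and accumulates post-burn-in
samples of $(x_1, x_2)$ from 200 seeded replicates into a 100 × 100
histogram over the occupied bounding box padded by 10%;
`potential_landscape()` then reports $U = -\ln P_{ss}$, its strict
8-neighbour minima, and whether the low-$U$ set encircles a hole — the
signature of a limit cycle.  The ring test runs on the full occupied
support of $P_{ss}$ by default: at $D = 10^{-6}$ the support converges
to the attractor itself, whereas a fixed potential-depth cut (offered as
an option) turned out to break genuine rings at fine bin resolutions,
because the dwell-time contrast between the slow and fast segments of
these cycles exceeds $e^2$ — the rings are, as one expects of
relaxation-like oscillations, strongly inhomogeneous.

Three reading choices are deliberate.  The noise "correlation tensor" is
taken as isotropic diagonal with the printed scalar strength, the
simplest reading consistent with a single $D$.  At $D = 10^{-6}$ the
noise cannot hop between basins on any feasible horizon, so $P_{ss}$ is
assembled from a multi-start ensemble (the same deterministic
initial-condition grid as the census); relative well depths therefore
reflect the uniform grid's basin shares, and depth statements are
*only* statements about $U$ values, never about basin volumes.  Whether
the published distributions were built from trajectory occupancy or from
endpoints alone is ambiguous; both modes are implemented
(`sample_mode = "occupancy"` is the default and records which was used).

## What the synthetic data does and does not emulate

The generator (`generate_fixtures()` and the Langevin ensembles) emulates
exactly the two data modalities of the original workflow: deterministic
trajectories from varied initial conditions at representative points of
each regime, and seeded noise-driven trajectories for occupancy
estimation.  It reproduces none of the things real recordings would add —
measurement noise, nonstationarity, finite sampling of unknown initial
conditions, parameter drift.  Passing tests therefore certify the
*dynamical* claims (bifurcation counts, regime geography, frequency
band, landscape topology) under the model's own assumptions, not the
model's fit to any experimental data.

## Numerical choices and problem sizes

* Root tolerance $10^{-9}$ (max-abs drift); continuation corrector
  $10^{-10}$; fold/Hopf refinement to about $10^{-10}$ in the parameter.
* Census horizon 3000 ms, transient fraction 0.5, oscillation threshold
  $10^{-3}$ activity units; doubled once on retry.
* The regime-map lattice censuses use a 0.2 ms reporting step (periods
  are tens of ms) and 400 Newton starts per point; the oracle tests use
  800–1600.
* Landscape defaults: 200 replicates × 3000 ms, burn-in 1500 ms,
  sampling every 1 ms, 100 × 100 bins.
* The acceptance computations run the full 71 × 71 map with curve
  tracing, six codim-1 scans, two 200-replicate landscapes and the
  property suite; these sizes were chosen so the entire analysis
  reproduces on a single desktop core in well under half an hour.

## Known limitations

* Unstable limit cycles and global (homoclinic/heteroclinic) bifurcations
  are not continued; the cycle–saddle collision on the strong-indirect
  slice is detected only as monotone period growth.
* No normal-form coefficients are computed; "supercritical" is verified
  empirically from the stable-cycle side of each Hopf point.
* Synaptic transmission delays, spiking dynamics and plasticity are out
  of scope; the model is a rate description with instantaneous coupling.
* Landscape well depths depend on the initial-condition grid (see above);
  they are reproducible but not ergodic averages.
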