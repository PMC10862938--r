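---
title: "Diffusion approximations for state-dependent diversification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion approximations for state-dependent diversification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffsse)
```

## The model

State-dependent speciation–extinction (SSE) models are branching processes
in which each lineage carries a discrete state and its speciation,
extinction, and state-transition rates depend on that state.  `diffsse`
works with the cladogenetic family (ClaSSE), in which state changes can
happen both along a lineage (anagenetically) and at the moment of
speciation, and focuses on its geographic special case, GeoSSE, where the
state of a species is its range: a nonempty subset of a finite set of
regions.  For regions $\{A, B\}$ the range states are $\{A\}$, $\{B\}$,
$\{A,B\}$; for $n$ regions there are $2^n - 1$ states, kept throughout in a
canonical order (by range size, then lexicographically).

Four event families drive the dynamics, with per-lineage rates:

* within-region speciation $w_\ell$ — a lineage occupying region $\ell$
  buds off a new endemic of $\{\ell\}$;
* dispersal $d_{k\ell}$ — a lineage occupying $k$ adds region $\ell$ to its
  range;
* between-region speciation $b_{st}$ — a widespread range splits into the
  two disjoint covering daughter ranges $s$ and $t$ (symmetric in $s, t$);
* local extinction $e_\ell$ — region $\ell$ drops out of a range; an
  endemic dies outright.

Instead of simulating trees, the package tracks the per-state lineage
counts $N_i(t)$.  Summing event rates over all source states gives, for
each state, a total gain rate $\mathbb{P}^+_i$ and loss rate
$\mathbb{P}^-_i$, both linear in the count vector.  The count diffusion has
infinitesimal mean and variance

$$\mu_i = \mathbb{P}^+_i - \mathbb{P}^-_i, \qquad
  \sigma^2_i = \mathbb{P}^+_i + \mathbb{P}^-_i,$$

and the state frequencies $\Pi_i = N_i / N$ inherit their infinitesimal
parameters through the multivariate Itô transform under the model's
assumption that the per-state counts are driven by independent noise (no
cross-covariances).  Both are exposed directly (`count_params()`,
`frequency_params()`, `ito_transform()`, `multivariate_ito()`), and the
identity between the frequency parameters and the Itô transform of
$N_i/N$ is enforced by tests at `1e-10` relative tolerance.

## Simulators

Three simulators share one rate implementation:

* `simulate_count_path()` — Euler–Maruyama on the count SDE: per state and
  step, an independent Gaussian increment with the current $\mu_i$,
  $\sigma_i$; counts falling below zero are clamped to exactly zero.
* `simulate_frequency_path()` — advances counts one step, rebuilds the
  finite-$N$ frequency drift and variance from the updated counts, advances
  the frequencies with their own increments, truncates to $[0,1]$ and
  renormalizes each row to sum one.  Total extinction aborts with an error
  (the frequency diffusion is undefined at $N = 0$).
* `simulate_jump_process()` — an exact Gillespie simulation of the count
  vector: every elementary event fires at its exact rate with exponential
  waiting times.  This is the tree-free equivalent of forward tree
  simulation and serves as the package's internal reference in place of an
  external tree simulator.  Optional survival conditioning rejects paths
  with $N(T) = 0$.

`ensemble()` replicates any of them with per-replicate seeds spawned
deterministically from one master seed and summarizes terminal means,
variances, and normal 95% intervals; `compare_ensembles()` applies the
Welch test of mean equality, the F-test of variance equality, and the
variance-ratio interval per state.

### What a green comparison does and does not establish

The diffusion is a Gaussian approximation.  Where all states start with
counts well above zero it reproduces the exact process' terminal means
within Monte-Carlo error, and the suite asserts this.  Where a state starts
at (or near) zero count, the clamp-negatives-to-zero rule is asymmetric and
inflates that state's mean: in the bundled full-event three-region scenario
(endemics starting at count 0, $N(0) = 40$), the exact mean of state
$\{A\}$ at $T = 10$ is 52.48 (computable as $e^{10A} N_0$ because the jump
process' means are linear), while the clamped diffusion gives about 53.5–54.6.
With 1000 replicates a Welch test has the power to detect this bias, so
the corresponding acceptance check is expected to fail for the endemic
states; the failure is a property of the stated simulation design, not a
defect of either simulator.  The frequency-path normalization introduces a
second, milder distortion of the same kind.  A step-size warning is raised
whenever the total event rate times the step exceeds 0.1.

## Stationary theory

In the large-$N$ limit the frequency noise vanishes and the dynamics reduce
to the ODE $d\Pi_i/dt = \hat{\mathbb{P}}^+_i - \hat{\mathbb{P}}^-_i$ in the
per-capita rates.  The package works with the reduced system in which the
last (full-range) state's frequency is eliminated as one minus the rest;
for GeoSSE this reduced system is affine, $\dot p = Mp + c$.

* `integrate_frequency_ode()` — fixed-step fourth-order Runge–Kutta on the
  reduced system (no external ODE solver is required; the system is small,
  smooth, and affine).  Grid density controls accuracy as $h^4$; at the
  default scales used in the tests the integrator agrees with the exact
  solution to better than `1e-7`.
* `solve_stationary_2region()` — for two regions, the eigen-decomposition
  of $M$ gives the closed form
  $\Pi(t) = C_1\nu_1 e^{\lambda_1 t} + C_2\nu_2 e^{\lambda_2 t} + K$ and
  the stationary point $K = -M^{-1}c$.  The textbook scalar constants
  (`numA`, `denomA`, `R`, `R1`, `R2`) are evaluated alongside for
  transparency; one of them (`R1`) circulates with an internally
  inconsistent coefficient pattern, so the eigen-decomposition — validated
  against the ODE integrator on hundreds of random rate sets — is the
  authoritative route, and `R1` is assembled with the coefficient pattern
  $4(w_A + b_{BA} + e_B)(w_B + b_{BA} + e_A)$ that the decomposition
  confirms.  The closed form is valid while $\Pi_A + \Pi_B \le 1$;
  trajectories violating that proviso are flagged.
* `stationary_by_eigen()` — the projection-matrix route: the dominant right
  eigenvector of the linear count dynamics $dN/dt = AN$, normalized to sum
  one (the stable stage distribution; the dominant eigenvalue is the
  overall growth rate).  The two routes answer subtly different questions —
  the ODE fixed point balances per-capita gains and losses state by state,
  the eigenvector balances them only up to overall growth — and they differ
  at the second to third decimal on the bundled comparison cases, exactly
  as the two published methods do.
* `time_to_stationarity()` — evaluates the deterministic trajectory on a
  uniform grid of `n_grid` points (default 1000, including both endpoints,
  so $\Delta t = T/(n_{grid}-1)$: the published mixing times are integer
  multiples of this spacing) and reports the first grid time at which the
  successive change of each state's frequency drops below `epsilon`
  (default `1e-9`).

### Two printed drift variants

The canonical large-$N$ drift is the plain per-capita difference
$\hat{\mathbb{P}}^+_i - \hat{\mathbb{P}}^-_i$; it is what the closed form,
the rate solving, and the published stationary numbers are built on, and it
is the package default everywhere.  The exact finite-$N$ drift, however,
retains the extra term $-\Pi_i \sum_j (\hat{\mathbb{P}}^+_j -
\hat{\mathbb{P}}^-_j)$ in the limit whenever total growth is nonzero.  Both
variants are exposed (`large_N_frequency_drift(variant = )`); they coincide
at any stationary point, which is also where the finite-$N$-to-limit
convergence tests are anchored so that both are tested honestly.  The
growth-compensated variant exists for cross-checks against the eigenvector
method and is never the default.

## Solving rates from frequencies

`solve_rates_for_frequencies()` inverts the map: given target stationary
frequencies, it finds strictly positive rates under which the target is a
fixed point and the state fluxes (total incoming minus outgoing rate
constants, `flux_total()`) respect the ordering of the target frequencies.
At fixed frequencies both conditions are linear and homogeneous in the rate
vector, so the solver computes the exact null space of the equality system
(SVD) and searches it for a strictly positive point satisfying the flux
inequalities by maximizing the worst slack from seeded random restarts.
Equality residuals are therefore at machine precision whenever the problem
is feasible, and different seeds land on genuinely different rate sets with
identical stationary behaviour — the many-to-one property that motivates
the analysis.  Solutions are scale-free and are normalized to a mean rate
of 0.1 unless the user pins specific rates via `fixed`.  Two closed-form
families with stationary point $(1/3, 1/3, 1/3)$ ship as
`rate_family_thirds()` together with an in-region sampler.

## Numerical choices and degenerate inputs

* Strict versus permissive validation: the rate-solving theory requires all
  rates strictly positive, but the simulation scenarios switch whole event
  classes off; `validate_params(strict = )` separates the two uses.
* Tie-breaks and tolerances: frequency normalization tolerance `1e-9`;
  stationarity residual threshold `1e-8`; flux inequality margin `1e-8`;
  mixing-time `epsilon` default `1e-9`.
* Initial counts from fractional caption frequencies use largest-remainder
  rounding by default (deterministic), with a seeded multinomial option.
* Degenerate dominant eigenspaces (complex or repeated leading eigenvalue)
  abort `stationary_by_eigen()` rather than returning an arbitrary vector;
  all-zero rate sets propagate zero drift and variance.

## Synthetic scenarios

`sse_fixtures()` bundles every worked configuration used in the
documentation and tests: four three-region simulation scenarios (speciation
only; speciation with dispersal; speciation with local extinction; all
events), four two-region equal-thirds panels with mixing-time settings, and
the two stationary-frequency comparison cases.  Scenario values are stated
once there and nowhere else.  One quoted rate ("$w_B \approx 0$" in the
first equal-thirds panel) is stored as its family value
$(-d_{AB} + 2e_B)/2 = 0.0005$, since a literal zero would leave the family.
These scenarios emulate idealized regimes — constant rates, independent
per-state noise, no sampling noise on the initial condition — and make no
attempt to mimic empirical reconstruction error, so green tests establish
internal consistency of the stochastic machinery and its deterministic
limits, not fidelity to any empirical system.

## Known limitations

* No time-varying (epoch) rates and no perturbation/re-equilibration
  analysis.
* No tree topology output: the framework is deliberately tree-free.
* The single-lineage (clade-origin) diffusion correction is not
  implemented; survival conditioning is available for the jump process
  only, as rejection sampling.
* The Euler–Maruyama clamp bias near zero counts discussed above.
* Only GeoSSE and BiSSE event taxonomies are provided; other ClaSSE
  variants (e.g. subset-sympatric cladogenesis) would need their own event
  tables.
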