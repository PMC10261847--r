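---
title: "Modelling emergency medical-supply allocation as a tripartite evolutionary game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling emergency medical-supply allocation as a tripartite evolutionary game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allocgame)
```

## The model

During a public health emergency, donated medical supplies typically flow
through a government-owned nonprofit organization (GNPO, e.g. a Red Cross
branch) that decides how to allocate them, hospitals that receive (or
dispute) the allocations, and a government that supervises the process.
None of the three can compute an optimal one-shot strategy: information is
incomplete and the situation changes faster than deliberation allows. The
package models them as three boundedly rational populations that adapt by
imitation, which leads to replicator dynamics over the strategy shares

- `x` — probability the allocator is *able to allocate on demand* (vs
  unable),
- `y` — probability the hospital *accepts* the plan (vs refuses and
  fights),
- `z` — probability the government supervises *strictly* (vs loosely),

each in `[0, 1]`, so the state lives in the unit cube.

Payoffs for the eight pure-strategy profiles are parameterized by 21
non-negative quantities in a common abstract payoff unit (no currency is
implied; only relative magnitudes matter): penalties on the allocator (`K1`,
`K2`), its reputation losses (`V1 < V2`) and opportunistic gain `A`,
coordination costs (`H1` for the allocator, `H2` for the hospital), hospital
losses (`D > E`), compensations extracted by a fighting hospital
(`W1 < W2`), the government's reward `B` and penalties (`P1 > P2`) on
hospitals, its social benefits (`R1`, `R2`), supervision costs
(`H4 > H5`), epidemic-control effort `H3`, the higher-authority
accountability loss `T > H4`, and the dimensionless fighting degree
`alpha` in `[0, 1]`. `validate_params()` checks all of these; the order
constraints are strict with zero tolerance by default because parameters
are user-supplied exact numbers and ties (e.g. `V1 = V2`) make the
threshold surfaces degenerate. Two relaxations exist and are deliberate:
generated scenarios demand a small margin `eps` instead, and sweep
execution accepts ties (`strict = FALSE`) because the printed sensitivity
grids themselves touch a boundary (`T = 100` with `H4 = 100`).

Each player's replicator equation has the form
`dx/dt = x (1 - x) [gain of the first strategy over the mixture]`, and the
three brackets have closed forms in the parameters. The package computes
the field twice, by design: `replicator_field()` implements the closed
forms, and `replicator_field_payoff()` derives the same quantities from
the payoff table through the expected payoffs. Their agreement (to 1e-9
relative, tested on random parameter sets and states) certifies the
simplifications; a transcription error in either route would surface
immediately. A consequence of the simplification is that `D`, `E`, `R1`,
`H1`, `H3` cancel: they shift payoff levels but not payoff *differences*,
so the dynamics are bit-identical under changes to them (also a test).

## Equilibria and stability

The eight cube corners are always rest points, and in an asymmetric game
only pure profiles can be evolutionarily stable, so classification reduces
to the corners (`pure_equilibria()`, `classify_equilibria()`). Interior
mixed rest points are detected (`interior_equilibria()`) and reported but
never classified as stable.

At a corner the Jacobian of the field is diagonal, so its eigenvalues have
exact closed forms in the parameters; `corner_eigenvalues()` evaluates
those forms, and the test suite confirms them against a numeric
eigendecomposition of the analytic Jacobian (itself validated against
central finite differences). Classification follows the Lyapunov indirect
method: all eigenvalue real parts below `-eps` gives an asymptotically
stable point (an ESS), any real part above `+eps` gives an unstable point,
and anything else is *critical* — the linearization is inconclusive and the
package reports exactly that rather than guessing. The band half-width
`eps` defaults to 1e-9: closed-form eigenvalues are exact in the
parameters, so the band only guards floating-point arithmetic on
user-supplied values.

Two parameter condition sets (`check_ess_conditions()`) characterize when
the two policy-relevant corners are stable: E3 = (0, 1, 0) (not on demand,
accept, loose) under condition set 1, and E8 = (1, 1, 1) (on demand,
accept, strict) under condition set 2. At the baseline both hold and the
system is bistable; from the symmetric start it converges to E8, as
`summary(allocation_game())` and the acceptance script recompute.

## The baseline case

The shipped baseline (`baseline_params()`) encodes an urban COVID-style
emergency-allocation scenario in abstract payoff units, with hospital
losses calibrated against the drop in inpatient revenue during an
outbreak (D = 300 against the background loss E = 200) and a moderate
fighting degree `alpha = 0.6`. At these values the closed-form eigenvalues
at E3 are (-25, -6, -10) and at E8 are (-35, -114, -10), the five
condition inequalities evaluate to (-6, -10, -35, -10, -114), and both
stable corners coexist.

## Threshold surfaces and preference volumes

Setting each bracket to zero yields a threshold surface in the opponents'
strategies (`thresholds()`): `y*(z)` for the allocator, `x*(z)` for the
hospital, `y**(x)` for the government. On one side of the surface the
player drifts to one pure strategy, on the other side to the alternative.
The surfaces are rational functions and can leave `[0, 1]` or blow up at a
denominator root; threshold evaluation therefore returns a tagged `NaN` at
a pole (with a `"singular_at"` attribute) instead of raising, so batch and
quadrature callers keep going. At the baseline `x*(z)` has a pole at
`z = 12/32`, which is also where the hospital bracket's slope in `x`
changes sign — the apparent monotonicity of the hospital's stability
function in `x` holds only below the pole, and the package's sign-law
tests use the correct orientation.

The volume of the cube on the attracting side of a surface is the
probability (under a uniform prior over states) of evolving toward the
corresponding pure strategy. Two conventions are implemented for the
allocator volume, and the package deliberately reports both:

- **unclipped**: the closed form `v_g1_closed()` (equivalently the
  quadrature `v_g1_integral()` of the unclipped threshold over
  `z` in `[A/K2, 1]`), which at the baseline gives 3325/3600 ≈ 0.9236 even
  though the threshold exceeds 1 on part of the range;
- **clipped/geometric**: `v_clipped()` integrates the threshold clipped
  into `[0, 1]`, the only convention that keeps every volume a genuine
  probability; at the baseline it gives 119/144 ≈ 0.8264.

The choice matters beyond the third decimal: the *sensitivity directions*
of the two variants disagree. Differentiating the clipped volume in the
fighting degree gives `+A^2 / (2 alpha^2 K2 (V2 - V1)) > 0` (more fighting
pushes the allocator toward on-demand allocation), while the unclipped
closed form gives the opposite sign at the baseline. The qualitative
policy statements about the allocator are consistent with the clipped
variant, which is what the package treats as the geometric probability;
`inference_signs()` reports central-difference derivatives of both so the
discrepancy is visible rather than hidden.

For the hospital and government volumes only the clipped convention is
defined at realistic parameters: their unclipped integrands are unbounded
at denominator roots (the hospital integrand has a non-integrable pole at
the baseline). A further honest caveat: at the baseline the clipped
hospital threshold is saturated at 0 below the pole and 1 above it, so the
whole derivative of that volume comes from the moving pole location
`z0 = (alpha W2 - alpha W1) / (B + alpha P2 - alpha P1)`. This makes
`dV_Q1/dB = 12/(B - 48)^2 > 0` and `dV_Q1/dP2 > 0` at the baseline —
*opposite* to the direction one would read off the integrand pointwise
(only the `P1` direction is negative). The package reports the computed
signs; the acceptance suite records the disagreement with the qualitative
claim rather than suppressing it.

Quadrature is a midpoint rule. Each preference-volume double integral has
one trivial axis (the integrand does not depend on it), so a 1-D midpoint
rule along the non-trivial axis with `n = 2001` cells is identical to the
2-D grid and self-converges below 1e-3 under refinement (tested). Grid
points landing exactly on a pole take the clip midpoint value 1/2, a
choice that vanishes with the cell width. For finite-difference
*derivatives* of the volumes a much finer grid is used
(`inference_signs()` defaults to 2e6 + 1 cells, still milliseconds in 1-D),
because a relative step of 1e-4 moves a clipped jump by less than a coarse
cell; derivatives below 10x the estimated quadrature noise are reported as
`"indeterminate"`, never as a guessed sign.

## Trajectories and the sensitivity sweeps

`integrate_game()` uses an adaptive solver (`deSolve::lsodar`, relative
tolerance 1e-8) with root-triggered early stopping when the field norm
falls below 1e-8, a horizon of 50 time units, and the symmetric-ignorance
start (0.5, 0.5, 0.5) by default; a 3x3x3 interior lattice
(`init_lattice()`) is available to probe basins. There is no canonical
choice of start, horizon or solver for replicator simulations of this
kind, so these are the package's own convergence-tested defaults, and
sweep outcomes should be read *qualitatively* (which corner a run
reaches, orderings across a grid), not as pointwise time series. The unit
cube is forward-invariant analytically; solver output is clamped and the
largest pre-clamp excursion is recorded (`clamp_excess`, observed around
1e-11, asserted below 1e-9). Halving the solver tolerances moves terminal
states by less than 1e-6.

`preset_sweeps()` carries the nine printed sensitivity grids verbatim
(`alpha` 0.1–0.9; `H2` 80–140; `H4` 70–130; `H5` 30–70; `T` 100–200; `K1`
40–120; `B` 40–120; `P1` 120–200; `A` 10–40) and `run_sweep()` integrates
each value from the default start, recording terminal and time-averaged
shares and the stability class of the terminal corner under the swept
parameter set. Sweep runs are deterministic. Two findings from running
them, both visible in the tests:

- `H5 = 40` is an exact degeneracy of the grid against the baseline
  (`H4 - H5 - R2 = 0`): E8 becomes non-hyperbolic, the edge
  `{(1, 1, z)}` is a line of equilibria, and the trajectory converges onto
  it at `z ≈ 0.884` — a rest point that is not an ESS. Every other preset
  run terminates at an ESS (E8, or E3 for large `H4`).
- The `H2` grid moves the on-demand transient by only ~1e-4 from the
  symmetric start, and in the *decreasing* direction: a costlier fight
  speeds the hospital toward acceptance, which lowers the allocator's
  payoff advantage. The qualitative claim that larger `H2` raises the
  on-demand share is start-state dependent and did not reproduce at any
  start we probed.

The `A` sweep's direction reversal around `A = 25` is likewise
start-dependent; the sweep summary exposes the per-value terminals so the
flip (if present for a given start) can be read off rather than asserted.

## Random scenarios

`sample_scenarios()` is the synthetic-data generator: parameters are drawn
independently and uniformly on per-parameter ranges (default ±50% around
the baseline, `alpha` clipped to `[0, 1]`), rejection-sampled against the
order constraints (with margin 1e-9) and optionally against either or both
stability condition sets. Independence and uniformity are deliberate
choices: the model treats parameters as free inputs without a dependence
structure, and uniform is the least-informative distribution on a range.
Identical seeds reproduce batches bit-for-bit; an acceptance rate below a
configurable floor (1e-4) after a bounded number of draws raises a
generation error instead of spinning. What the generator emulates is the
*inequality structure* of plausible emergency-allocation scenarios, not
any empirical joint distribution of real penalties and costs — passing
tests on generated scenarios certifies the mathematics (oracle identities,
eigenvalue forms, condition-classification equivalence) across the valid
parameter region, not calibration to real data.

## Problem sizes and limitations

The test suite and acceptance script use 100-scenario batches for the
property checks, 1000 random (parameter, state) pairs for the field
oracle, 2001-cell quadrature for volumes, a 27-point lattice for the basin
probe, and the 51 preset sweep runs; all are the package's own choices and
run in well under a minute on one CPU.

Known limitations: no stochastic (finite-population) dynamics and no
time-varying parameters; critical (non-hyperbolic) corners are reported
but not resolved by center-manifold analysis; interior rest points are
located but not classified; the hospital/government preference volumes
have no closed forms, so only quadrature values are available; and the
model's payoff units are abstract, so magnitudes are only meaningful
relative to one another.
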