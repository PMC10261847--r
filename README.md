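# allocgame

Tripartite evolutionary game analysis of emergency medical-supply
allocation.

During a public health emergency (the motivating case is the COVID-19
outbreak in a large city), donated medical supplies flow through a
government-owned nonprofit allocator (GNPO), hospitals that receive the
allocations, and a government that supervises the process. All three are
boundedly rational and adapt by imitation, so the package models the
strategy shares

- `x` — GNPO allocates *on demand* (vs unable to),
- `y` — hospital *accepts* (vs refuses and fights),
- `z` — government supervises *strictly* (vs loosely),

with replicator dynamics on the unit cube,

```
dx/dt = x(1-x) [ (1-y) a (V2 - V1) + z K2 - A ]
dy/dt = y(1-y) [ z ((1-x)B + x a P1 + (1-x) a P2) + a H2 - (1-x) a W2 - x a W1 ]
dz/dt = z(1-z) [ gz(x, y) ]
```

where the brackets are each player's payoff advantage derived from an
eight-profile payoff matrix over 21 non-negative parameters (penalties
`K1, K2, P1, P2`, reputation losses `V1 < V2`, rewards and compensations
`B, W1 < W2`, costs `H1..H5`, benefits `R1, R2`, losses `D > E`,
accountability `T > H4`, opportunistic gain `A`, fighting degree
`alpha` in `[0,1]`). The package provides:

- the payoff matrix and expected payoffs (`payoff_table()`,
  `expected_payoffs()`), with the replicator field computed both from the
  closed forms and independently from the payoff table;
- equilibrium enumeration and Lyapunov (indirect method) stability
  classification with exact closed-form corner eigenvalues
  (`classify_equilibria()`, `corner_eigenvalues()`,
  `check_ess_conditions()`);
- threshold surfaces and strategy-preference volumes by quadrature, in
  both the unclipped and the clipped/probability conventions
  (`thresholds()`, `volume_report()`, `inference_signs()`);
- trajectory integration and the nine preset parameter-sensitivity sweeps
  (`integrate_game()`, `preset_sweeps()`, `run_sweep()`);
- a seeded generator of random valid scenarios (`sample_scenarios()`).

## Worked example

```r
library(allocgame)

g <- allocation_game()          # baseline parameter set
summary(g, n = 501)
```

```
Corner equilibria (Lyapunov indirect method):
 point x y z lambda_x lambda_y lambda_z    class
    E1 0 0 0        5        6      348 unstable
    E2 1 0 0       -5       18      336 unstable
    E3 0 1 0      -25       -6      -10      ESS
    E4 0 0 1       65      134     -348 unstable
    E5 1 1 0       25      -18       10 unstable
    E6 1 0 1      -65      114     -336 unstable
    E7 0 1 1       35     -134       10 unstable
    E8 1 1 1      -35     -114      -10      ESS
ESS: E3, E8
```

The baseline is bistable: the socially desirable corner E8 (allocate on
demand, accept, strict supervision) and the complacent corner E3 (unable
to allocate on demand, accept, loose supervision) are both evolutionarily
stable; which one the system reaches depends on where it starts. From the
symmetric start the system reaches E8:

```r
tr <- integrate_game(baseline_params())
tr
#> Replicator trajectory from (0.5, 0.5, 0.5), 20 time points over [0, 1.880719]
#>   terminal state: (1, 1, 0.999999999) [E8]
#>   converged: TRUE (field norm 1e-08)
```

Strategy-preference volumes (probabilities of drifting toward each pure
strategy under a uniform prior over states):

```r
volume_report(baseline_params())
#> Strategy-preference volumes (grid 2001):
#>   allocator   V_G1 = 0.923611 (unclipped; quadrature 0.923611), clipped 0.826389
#>   hospital    V_Q1 = 0.625187 (refuse-and-fight), V_Q2 = 0.374813
#>   government  V_N1 = 0.992910 (strict), V_N2 = 0.007090
```

The two allocator values reflect two integration conventions (clipping the
threshold surface into the cube versus integrating it unclipped); the
vignette discusses why the package reports both and how their sensitivity
directions differ.

Sensitivity sweeps over the preset grids:

```r
res <- run_sweep(preset_sweeps()$H4)
res$summary[, c("value", "terminal_corner", "corner_class")]
```

Small strict-supervision costs lead to E8; when `H4` grows past the
stability boundary the system falls back to E3.

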