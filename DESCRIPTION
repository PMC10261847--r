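Package: allocgame
Title: Tripartite Evolutionary Game Analysis of Emergency Medical-Supply Allocation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the tripartite evolutionary game played by a
    government-owned nonprofit allocator of donated medical supplies, the
    hospitals that receive them, and the government supervising the allocation
    during a public health emergency. Builds the eight-profile payoff matrix,
    evaluates expected payoffs and replicator dynamics for the three bounded-
    rationality players, enumerates pure-strategy equilibria and classifies
    their stability by the Lyapunov indirect method (closed-form Jacobian
    eigenvalues cross-checked numerically), computes strategy-preference
    volumes of the phase diagrams by quadrature, and reproduces parameter-
    sensitivity sweeps of the replicator system as seeded, reproducible batch
    runs with CSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
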