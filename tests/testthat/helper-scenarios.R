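# Shared fixtures: random valid scenarios and a finite-difference Jacobian
# used as an independent oracle.

random_scenarios <- function(n, seed, enforce = "none") {
  sample_scenarios(n, seed = seed, enforce = enforce)$params
}

random_states <- function(n, seed, lo = 0.05, hi = 0.95) {
  set.seed(seed)
  matrix(runif(3 * n, lo, hi), ncol = 3)
}

fd_jacobian <- function(p, s, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- s; dn <- s
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (replicator_field(p, up) - replicator_field(p, dn)) / (2 * h)
  }
  J
}
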