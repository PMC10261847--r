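# Replicator dynamics of the tripartite game: closed-form vector field,
# the threshold surfaces separating each player's basins, and trajectory
# integration on the unit cube.

# Brackets of the three replicator equations: F(x) = x(1-x) gx(y,z) etc.
# D, E, R1, H1, H3 cancel out of these expressions although they appear in
# the payoff table.
.bracket_x <- function(p, y, z) {
  a <- p[["alpha"]]
  y * (a * p[["V1"]] - a * p[["V2"]]) + a * p[["V2"]] - a * p[["V1"]] +
    z * p[["K2"]] - p[["A"]]
}

.bracket_y <- function(p, x, z) {
  a <- p[["alpha"]]
  z * (x * a * p[["P1"]] - x * a * p[["P2"]] - x * p[["B"]] + p[["B"]] + a * p[["P2"]]) +
    x * (a * p[["W2"]] - a * p[["W1"]]) + a * p[["H2"]] - a * p[["W2"]]
}

.bracket_z <- function(p, x, y) {
  a <- p[["alpha"]]
  p[["R2"]] + p[["K1"]] + p[["K2"]] - p[["H4"]] + p[["H5"]] + p[["T"]] + a * p[["P2"]] +
    x * (a * p[["P1"]] - a * p[["P2"]] - p[["K2"]]) +
    y * (-p[["B"]] - a * p[["P2"]] - p[["K1"]] - p[["T"]]) +
    x * y * (p[["B"]] - a * p[["P1"]] + a * p[["P2"]])
}

#' Replicator vector field (closed form)
#'
#' Time derivatives of the strategy shares under replicator dynamics:
#' `dx/dt = x(1-x) gx(y,z)`, `dy/dt = y(1-y) gy(x,z)`,
#' `dz/dt = z(1-z) gz(x,y)`, where each bracket is the payoff advantage of
#' the player's first pure strategy over its alternative.
#'
#' @param p A valid `"game_params"` vector.
#' @param s State `(x, y, z)` in the unit cube.
#' @return Named numeric vector `c(dx, dy, dz)` (probability per time unit).
#' @examples
#' replicator_field(baseline_params(), c(0.5, 0.5, 0.5))  # (5, 17, 42.75)
#' @export
replicator_field <- function(p, s) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  s <- .check_state(s)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  c(dx = x * (1 - x) * .bracket_x(p, y, z),
    dy = y * (1 - y) * .bracket_y(p, x, z),
    dz = z * (1 - z) * .bracket_z(p, x, y))
}

#' Replicator vector field from the payoff table (oracle form)
#'
#' Computes `(x (E11 - E1), y (E21 - E2), z (E31 - E3))` directly from the
#' expected payoffs of [expected_payoffs()].  Algebraically identical to
#' [replicator_field()]; kept as an independent route so the closed-form
#' simplifications can be certified against the payoff table.
#'
#' @inheritParams replicator_field
#' @return Named numeric vector `c(dx, dy, dz)`.
#' @export
replicator_field_payoff <- function(p, s) {
  e <- expected_payoffs(p, s)
  s <- .check_state(s)
  c(dx = s[["x"]] * (e$E11 - e$E1),
    dy = s[["y"]] * (e$E21 - e$E2),
    dz = s[["z"]] * (e$E31 - e$E3))
}

.safe_ratio <- function(num, den) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  out <- num / den
  out[den == 0] <- NaN
  sing <- which(den == 0)
  if (length(sing)) attr(out, "singular_at") <- sing
  out
}

#' Threshold surfaces of the three players
#'
#' Returns the loci where each player's replicator bracket vanishes, as
#' vectorized functions of the opponents' strategy shares:
#' \describe{
#'   \item{`y_star(z)`}{hospital-acceptance threshold for the allocator;
#'     for `y` below it the allocator drifts toward on-demand allocation.}
#'   \item{`x_star(z)`}{allocator threshold for the hospital; for `x` above
#'     it the hospital drifts toward acceptance.}
#'   \item{`y_double_star(x)`}{acceptance threshold for the government; for
#'     `y` below it the government drifts toward strict supervision.}
#' }
#' Values may fall outside \[0, 1\] (callers clip as needed).  A zero
#' denominator at a requested argument yields `NaN` with a `"singular_at"`
#' attribute marking the offending positions, rather than an error, so
#' batch evaluation continues.  The allocator surface is tangent to the
#' cube's top face at `z = A/K2` (`y_star(A/K2) = 1`).
#'
#' @param p A valid `"game_params"` vector.
#' @return List of class `"threshold_surfaces"` with elements `y_star`,
#'   `x_star`, `y_double_star` (functions) and `z_tangent = A/K2`.
#' @examples
#' th <- thresholds(baseline_params())
#' th$y_star(25 / 60)   # exactly 1
#' @export
thresholds <- function(p) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  a <- p[["alpha"]]
  force(p)
  y_star <- function(z) {
    .safe_ratio(a * p[["V1"]] - a * p[["V2"]] - z * p[["K2"]] + p[["A"]],
                a * p[["V1"]] - a * p[["V2"]])
  }
  x_star <- function(z) {
    .safe_ratio(z * (p[["B"]] + a * p[["P2"]]) - a * p[["W2"]] + a * p[["H2"]],
                z * (a * p[["P2"]] - a * p[["P1"]] + p[["B"]]) +
                  a * p[["W1"]] - a * p[["W2"]])
  }
  y_double_star <- function(x) {
    .safe_ratio(p[["H4"]] - p[["R2"]] - p[["K1"]] - p[["K2"]] - p[["H5"]] -
                  p[["T"]] - a * p[["P2"]] -
                  x * (a * p[["P1"]] - a * p[["P2"]] - p[["K2"]]),
                x * (p[["B"]] + a * p[["P2"]] - a * p[["P1"]]) -
                  p[["B"]] - a * p[["P2"]] - p[["K1"]] - p[["T"]])
  }
  structure(list(y_star = y_star, x_star = x_star,
                 y_double_star = y_double_star,
                 z_tangent = if (p[["K2"]] > 0) p[["A"]] / p[["K2"]] else NaN),
            class = "threshold_surfaces")
}

#' Integrate a replicator trajectory
#'
#' Integrates the replicator field from `s0` with an adaptive solver
#' (`deSolve::lsodar`), stopping early once the field norm drops below
#' `field_tol`.  States are numerically clamped to the unit cube (the cube
#' is forward-invariant analytically; clamping only removes solver-level
#' round-off excursions).
#'
#' @param p A valid `"game_params"` vector.
#' @param s0 Initial state in the unit cube (default: the symmetric-prior
#'   cube centre `(0.5, 0.5, 0.5)`).
#' @param horizon Integration horizon in model time units.
#' @param n_steps Number of output time points.
#' @param rtol,atol Solver tolerances.
#' @param field_tol Early-stop threshold on the Euclidean field norm; also
#'   defines the `converged` flag.
#' @return Object of class `"game_trajectory"`: a list with `states`
#'   (data frame `t`, `x`, `y`, `z`), `params`, `s0`, `converged`,
#'   `terminal` (final state), `terminal_norm`, `terminal_corner`
#'   (label `E1`..`E8` if the final state is within 1e-3 of a corner,
#'   otherwise `NA`), and `clamp_excess` (largest distance any raw solver
#'   state lay outside the cube before clamping).
#' @examples
#' tr <- integrate_game(baseline_params())
#' tr$terminal_corner
#' @export
integrate_game <- function(p, s0 = c(0.5, 0.5, 0.5), horizon = 50,
                           n_steps = 501, rtol = 1e-8, atol = 1e-10,
                           field_tol = 1e-8) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  s0 <- .check_state(s0)
  times <- seq(0, horizon, length.out = n_steps)
  deriv <- function(t, state, parms) {
    state <- pmin(pmax(state, 0), 1)
    list(unname(replicator_field(p, state)))
  }
  root <- function(t, state, parms) {
    state <- pmin(pmax(state, 0), 1)
    sqrt(sum(replicator_field(p, state)^2)) - field_tol
  }
  sol <- tryCatch(
    deSolve::lsodar(y = unname(s0), times = times, func = deriv,
                    parms = NULL, rtol = rtol, atol = atol, rootfunc = root),
    error = function(e) {
      stop("replicator integration failed: ", conditionMessage(e),
           call. = FALSE)
    })
  states <- as.data.frame(sol)
  names(states) <- c("t", "x", "y", "z")
  raw <- as.matrix(states[, c("x", "y", "z")])
  clamp_excess <- max(0, max(raw - 1), max(-raw))
  states$x <- pmin(pmax(states$x, 0), 1)
  states$y <- pmin(pmax(states$y, 0), 1)
  states$z <- pmin(pmax(states$z, 0), 1)
  terminal <- c(x = states$x[nrow(states)], y = states$y[nrow(states)],
                z = states$z[nrow(states)])
  tnorm <- sqrt(sum(replicator_field(p, terminal)^2))
  corners <- pure_equilibria()
  d <- sqrt(rowSums(sweep(corners, 2L, terminal)^2))
  corner <- if (min(d) < 1e-3) rownames(corners)[which.min(d)] else NA_character_
  structure(list(states = states, params = p, s0 = s0,
                 converged = tnorm < field_tol, terminal = terminal,
                 terminal_norm = tnorm, terminal_corner = corner,
                 clamp_excess = clamp_excess,
                 settings = list(horizon = horizon, n_steps = n_steps,
                                 rtol = rtol, atol = atol,
                                 field_tol = field_tol)),
            class = "game_trajectory")
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat("Replicator trajectory from (", paste(signif(x$s0, 4), collapse = ", "),
      "), ", nrow(x$states), " time points over [0, ",
      max(x$states$t), "]\n", sep = "")
  cat("  terminal state: (", paste(signif(x$terminal, 6), collapse = ", "),
      ")", if (!is.na(x$terminal_corner)) paste0(" [", x$terminal_corner, "]"),
      "\n  converged: ", x$converged,
      " (field norm ", signif(x$terminal_norm, 3), ")\n", sep = "")
  invisible(x)
}

#' Export a trajectory to CSV (with a JSON metadata sidecar)
#'
#' Writes columns `t`, `x`, `y`, `z` to `path` and the run metadata
#' (parameters, initial state, solver settings) to `<path>.json`.
#'
#' @param tr A `"game_trajectory"`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(tr, path) {
  stopifnot(inherits(tr, "game_trajectory"))
  utils::write.csv(tr$states, path, row.names = FALSE, quote = FALSE)
  meta <- list(params = as.list(unclass(tr$params)), s0 = as.list(tr$s0),
               settings = tr$settings, converged = tr$converged,
               terminal = as.list(tr$terminal),
               terminal_corner = tr$terminal_corner)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
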