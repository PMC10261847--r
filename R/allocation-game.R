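# Central S3 class tying the modules together: an allocation_game couples
# a parameter set with its payoff table, and the generic methods expose
# stability analysis (summary), trajectory simulation (simulate) and
# plotting in the classic modelling idiom.

#' Construct a tripartite allocation game
#'
#' Couples a parameter set with its eight-profile payoff table.  The
#' returned object is the entry point for the analysis generics:
#' `summary()` classifies the corner equilibria, `simulate()` integrates
#' replicator trajectories, `plot()` draws them, and `coef()` returns the
#' parameters.
#'
#' @param params A `"game_params"` vector (default: the baseline case).
#' @return Object of class `"allocation_game"` with elements `params` and
#'   `payoffs`.
#' @examples
#' g <- allocation_game()
#' summary(g)
#' @export
allocation_game <- function(params = baseline_params()) {
  if (!inherits(params, "game_params")) params <- game_params(.values = params)
  .stop_if_invalid(params, strict = FALSE)
  structure(list(params = params, payoffs = payoff_table(params)),
            class = "allocation_game")
}

#' @export
print.allocation_game <- function(x, ...) {
  cat("Tripartite medical-supply allocation game\n")
  cat("Players: allocator (able/unable on demand), hospital (accept/refuse),",
      "government (strict/loose)\n")
  cat("Parameters (payoff units):\n")
  print(unclass(x$params))
  cond <- check_ess_conditions(x$params)
  cat("Stability conditions: set 1 ",
      if (attr(cond, "condition1")) "holds" else "fails",
      ", set 2 ", if (attr(cond, "condition2")) "holds" else "fails",
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.allocation_game <- function(object, ...) object$params

#' Summarize an allocation game
#'
#' Classifies the eight corner equilibria by the Lyapunov indirect method,
#' evaluates the two stability condition sets, detects interior rest
#' points, and reports the strategy-preference volumes.
#'
#' @param object An `"allocation_game"`.
#' @param eps Zero band for eigenvalue real parts.
#' @param n Quadrature cells for the volumes.
#' @param ... Unused.
#' @return Object of class `"summary.allocation_game"`.
#' @export
summary.allocation_game <- function(object, eps = 1e-9, n = 2001, ...) {
  structure(list(
    params = object$params,
    equilibria = classify_equilibria(object$params, eps = eps,
                                     interior = TRUE),
    volumes = volume_report(object$params, n = n)),
    class = "summary.allocation_game")
}

#' @export
print.summary.allocation_game <- function(x, ...) {
  print(x$equilibria)
  cond <- attr(x$equilibria, "conditions")
  print(cond)
  print(x$volumes)
  invisible(x)
}

#' Simulate replicator trajectories of an allocation game
#'
#' Integrates the replicator dynamics from `nsim` initial states.  With
#' `init = NULL` and `nsim = 1` the symmetric cube centre is used; for
#' `nsim > 1`, initial states are drawn uniformly from the open cube
#' (seeded, reproducible).
#'
#' @param object An `"allocation_game"`.
#' @param nsim Number of trajectories.
#' @param seed Optional integer seed for random initial states.
#' @param init Optional matrix of initial states (rows `(x, y, z)`),
#'   overriding random draws; e.g. [init_lattice()].
#' @param horizon,field_tol Passed to [integrate_game()].
#' @param ... Unused.
#' @return List of `"game_trajectory"` objects (length `nsim` or
#'   `nrow(init)`).
#' @export
simulate.allocation_game <- function(object, nsim = 1, seed = NULL,
                                     init = NULL, horizon = 50,
                                     field_tol = 1e-8, ...) {
  if (is.null(init)) {
    if (nsim == 1L) {
      init <- matrix(c(0.5, 0.5, 0.5), nrow = 1)
    } else {
      if (!is.null(seed)) {
        old_seed <- if (exists(".Random.seed", envir = globalenv())) {
          get(".Random.seed", envir = globalenv())
        } else NULL
        on.exit({
          if (!is.null(old_seed)) {
            assign(".Random.seed", old_seed, envir = globalenv())
          }
        })
        set.seed(as.integer(seed))
      }
      init <- matrix(stats::runif(3 * nsim, 0.05, 0.95), ncol = 3)
    }
  }
  if (is.numeric(init) && is.null(dim(init))) init <- matrix(init, nrow = 1)
  lapply(seq_len(nrow(init)), function(i) {
    integrate_game(object$params, s0 = init[i, ], horizon = horizon,
                   field_tol = field_tol)
  })
}

#' Plot an allocation game trajectory
#'
#' Integrates (or accepts) a trajectory and draws the three strategy
#' shares against time.
#'
#' @param x An `"allocation_game"`.
#' @param s0 Initial state.
#' @param horizon Integration horizon.
#' @param ... Passed to [graphics::matplot()].
#' @return The trajectory, invisibly.
#' @export
plot.allocation_game <- function(x, s0 = c(0.5, 0.5, 0.5), horizon = 50,
                                 ...) {
  tr <- integrate_game(x$params, s0 = s0, horizon = horizon)
  plot(tr, ...)
  invisible(tr)
}

#' @export
plot.game_trajectory <- function(x, ...) {
  graphics::matplot(x$states$t, as.matrix(x$states[, c("x", "y", "z")]),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#D55E00", "#0072B2", "#009E73"),
                    xlab = "time", ylab = "strategy share", ylim = c(0, 1),
                    ...)
  graphics::legend("right",
                   legend = c("x: able on demand", "y: accept",
                              "z: strict supervision"),
                   col = c("#D55E00", "#0072B2", "#009E73"),
                   lty = 1, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
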