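# Parameter handling for the tripartite supply-allocation game.
#
# All 21 payoff parameters live in a named numeric vector of class
# "game_params".  Payoff units are abstract: the model never fixes a
# currency, only the relative magnitudes matter.

#' Names of the 21 game parameters
#'
#' The canonical ordering used throughout the package and in serialized
#' configurations.
#'
#' @return Character vector of length 21.
#' @export
param_names <- function() {
  c("K1", "K2", "V1", "V2", "A", "H1", "D", "E", "alpha",
    "W1", "W2", "B", "P1", "P2", "H2", "R1", "H3", "H4", "H5", "R2", "T")
}

#' Construct a parameter set for the allocation game
#'
#' Builds the full 21-parameter set of the tripartite game.  Any parameter
#' not supplied defaults to its baseline value (see [baseline_params()]), so
#' `game_params(A = 70)` is the baseline with the opportunistic gain raised
#' to 70.
#'
#' Parameter meaning (all in abstract payoff units unless noted):
#' \describe{
#'   \item{K1, K2}{government penalties on the allocator (GNPO): K1 for
#'     hospital conflict under strict supervision, K2 for failing to
#'     allocate on demand.}
#'   \item{V1, V2}{GNPO reputation losses when the hospital fights, under
#'     on-demand (V1) and not-on-demand (V2 > V1) allocation.}
#'   \item{A}{GNPO's opportunistic gain from not allocating on demand.}
#'   \item{H1}{GNPO's coordination cost when the hospital fights.}
#'   \item{D, E}{hospital losses: D from an unmet allocation, E from the
#'     general early-epidemic shortage (D > E).}
#'   \item{alpha}{degree of hospital fighting, dimensionless in \[0, 1\].}
#'   \item{W1, W2}{supply compensation the fighting hospital extracts from
#'     the GNPO (W1 < W2).}
#'   \item{B}{government reward to a hospital that accepts a not-on-demand
#'     plan under strict supervision.}
#'   \item{P1, P2}{government penalties on a fighting hospital (P1 > P2).}
#'   \item{H2}{hospital's own cost of fighting.}
#'   \item{R1, R2}{government social benefits: R1 from on-demand allocation,
#'     R2 credibility gain from strict supervision.}
#'   \item{H3}{government's extra epidemic-control cost after a
#'     not-on-demand allocation.}
#'   \item{H4, H5}{cost of strict (H4) vs loose (H5 < H4) supervision.}
#'   \item{T}{higher-authority accountability loss under loose supervision
#'     when hospitals fight (T > H4).}
#' }
#'
#' @param ... Named parameter overrides, e.g. `alpha = 0.4`.
#' @param .values Optional full named numeric vector/list used instead of
#'   the baseline as the starting point.
#' @return A named numeric vector of class `"game_params"`.
#' @seealso [baseline_params()], [validate_params()]
#' @examples
#' p <- game_params(A = 70)
#' p[["A"]]
#' @export
game_params <- function(..., .values = NULL) {
  base <- if (is.null(.values)) .baseline_values() else unlist(.values)
  over <- list(...)
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("all arguments to game_params() must be named", call. = FALSE)
    }
    bad <- setdiff(nm, param_names())
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (k in nm) base[[k]] <- as.numeric(over[[k]])
  }
  missing <- setdiff(param_names(), names(base))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- as.numeric(base[param_names()])
  names(p) <- param_names()
  for (k in param_names()) {
    if (!is.finite(p[[k]])) {
      stop("parameter '", k, "' is missing or non-finite", call. = FALSE)
    }
  }
  structure(p, class = "game_params")
}

.baseline_values <- function() {
  c(K1 = 80, K2 = 60, V1 = 100, V2 = 150, A = 25, H1 = 80, D = 300, E = 200,
    alpha = 0.6, W1 = 80, W2 = 100, B = 80, P1 = 160, P2 = 80, H2 = 110,
    R1 = 170, H3 = 160, H4 = 100, H5 = 50, R2 = 60, T = 150)
}

#' Baseline parameter set of the computational case
#'
#' The parameter values used for the worked numerical case (Wuhan-style
#' emergency allocation scenario): K1=80, K2=60, V1=100, V2=150, A=25,
#' H1=80, D=300, E=200, alpha=0.6, W1=80, W2=100, B=80, P1=160, P2=80,
#' H2=110, R1=170, H3=160, H4=100, H5=50, R2=60, T=150.
#'
#' @return A `"game_params"` vector.
#' @examples
#' baseline_params()
#' @export
baseline_params <- function() {
  structure(.baseline_values(), class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat("Tripartite allocation-game parameters (payoff units):\n")
  print(unclass(x), ...)
  rep <- validate_params(x)
  cat(if (attr(rep, "valid")) "All model constraints satisfied.\n"
      else "WARNING: model constraints violated (see validate_params()).\n")
  invisible(x)
}

# Constraint table used by validate_params(); the order constraints are
# strict inequalities lhs > rhs.
.order_constraints <- function() {
  list(c("V2 > V1", "V2", "V1"),
       c("W2 > W1", "W2", "W1"),
       c("P1 > P2", "P1", "P2"),
       c("D > E",   "D",  "E"),
       c("H4 > H5", "H4", "H5"),
       c("T > H4",  "T",  "H4"))
}

#' Validate a parameter set against the model's constraints
#'
#' Checks the order constraints of the model (V2 > V1, W2 > W1, P1 > P2,
#' D > E, H4 > H5, T > H4), non-negativity of every payoff parameter, and
#' the range 0 <= alpha <= 1.  Strict inequalities are checked with zero
#' tolerance by default; `eps > 0` demands a margin (used when generating
#' random scenarios), and `strict = FALSE` accepts ties (useful for sweep
#' values that sit exactly on a boundary).
#'
#' @param p A `"game_params"` vector (or coercible named vector).
#' @param strict Logical; if `FALSE` the order constraints pass on ties.
#' @param eps Non-negative margin required of the strict inequalities.
#' @return A data frame of class `"constraint_report"` with columns
#'   `constraint`, `lhs`, `rhs`, `satisfied` and an attribute `valid`
#'   (conjunction of all rows).
#' @examples
#' validate_params(baseline_params())
#' r <- validate_params(game_params(V1 = 100, V2 = 100))
#' attr(r, "valid")
#' @export
validate_params <- function(p, strict = TRUE, eps = 0) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  rows <- list()
  for (cc in .order_constraints()) {
    lhs <- p[[cc[2]]]; rhs <- p[[cc[3]]]
    ok <- if (strict) lhs > rhs + eps else lhs >= rhs
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = cc[1], lhs = lhs, rhs = rhs, satisfied = ok)
  }
  for (k in setdiff(param_names(), "alpha")) {
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = paste0(k, " >= 0"), lhs = p[[k]], rhs = 0,
      satisfied = p[[k]] >= 0)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    constraint = "0 <= alpha <= 1", lhs = p[["alpha"]], rhs = NA_real_,
    satisfied = p[["alpha"]] >= 0 && p[["alpha"]] <= 1)
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("constraint_report", "data.frame")
  attr(rep, "valid") <- all(rep$satisfied)
  rep
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("Constraint report (valid = ", attr(x, "valid"), "):\n", sep = "")
  bad <- x[!x$satisfied, , drop = FALSE]
  if (nrow(bad) == 0L) {
    cat("  all ", nrow(x), " constraints satisfied\n", sep = "")
  } else {
    print.data.frame(bad, row.names = FALSE)
  }
  invisible(x)
}

#' Test whether a parameter set is valid
#'
#' @inheritParams validate_params
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_params <- function(p, strict = TRUE, eps = 0) {
  attr(validate_params(p, strict = strict, eps = eps), "valid")
}

.stop_if_invalid <- function(p, strict = TRUE) {
  rep <- validate_params(p, strict = strict)
  if (!attr(rep, "valid")) {
    bad <- rep$constraint[!rep$satisfied]
    stop("invalid parameter set; violated: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

#' Read a parameter configuration from JSON
#'
#' The file must be a flat JSON object keyed exactly by the 21 parameter
#' names; missing or unknown keys are an error naming the key.  The loaded
#' set is validated (non-finite values rejected); order-constraint
#' violations produce a warning, not an error, so that deliberately
#' degenerate configurations can still be loaded and inspected.
#'
#' @param path Path to a JSON file.
#' @return A `"game_params"` vector.
#' @seealso [write_params()]
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- names(obj)
  extra <- setdiff(nm, param_names())
  if (length(extra)) {
    stop("unknown key(s) in '", path, "': ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(param_names(), nm)
  if (length(missing)) {
    stop("missing key(s) in '", path, "': ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- game_params(.values = obj)
  if (!is_valid_params(p)) {
    warning("loaded parameter set violates model constraints", call. = FALSE)
  }
  p
}

#' Write a parameter configuration to JSON
#'
#' @param p A `"game_params"` vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_params()]
#' @export
write_params <- function(p, path) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  jsonlite::write_json(as.list(unclass(p)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default sampling ranges for random scenarios
#'
#' Each payoff parameter ranges over +/-50% of its baseline value; the
#' fighting degree `alpha` is clipped into \[0, 1\].
#'
#' @param spread Half-width as a fraction of the baseline value.
#' @return Named list of `c(lo, hi)` ranges.
#' @export
default_ranges <- function(spread = 0.5) {
  base <- .baseline_values()
  r <- lapply(param_names(), function(k) {
    lo <- base[[k]] * (1 - spread); hi <- base[[k]] * (1 + spread)
    if (k == "alpha") c(max(0, lo), min(1, hi)) else c(max(0, lo), hi)
  })
  names(r) <- param_names()
  r
}

#' Sample random valid parameter scenarios
#'
#' Draws parameter sets independently and uniformly on the given ranges and
#' rejection-samples until `n` sets satisfy the model's constraints (with
#' margin `eps`) and, optionally, the stability condition sets under which
#' the two evolutionarily stable corners exist: `"condition1"` (the
#' accept/loose corner E3 is stable), `"condition2"` (the on-demand/accept/
#' strict corner E8 is stable), or `"both"`.
#'
#' Sampling is driven entirely by `seed`: the same `(n, seed, ranges,
#' enforce)` call reproduces the same batch bit-for-bit.
#'
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed.
#' @param ranges Named list of `c(lo, hi)` per parameter; see
#'   [default_ranges()].
#' @param enforce One of `"none"`, `"condition1"`, `"condition2"`, `"both"`.
#' @param eps Strictness margin passed to [validate_params()].
#' @param floor Minimum tolerated acceptance rate; if after `max_draws`
#'   candidate draws the acceptance rate is below this floor a generation
#'   error is raised.
#' @param max_draws Upper bound on candidate draws.
#' @return A list of class `"scenario_batch"`: `params` (list of
#'   `"game_params"`), `seed`, `ranges`, `enforce`, `acceptance_rate`.
#' @examples
#' b <- sample_scenarios(5, seed = 1)
#' length(b$params)
#' @export
sample_scenarios <- function(n, seed, ranges = default_ranges(),
                             enforce = c("none", "condition1", "condition2", "both"),
                             eps = 1e-9, floor = 1e-4, max_draws = 2e6) {
  enforce <- match.arg(enforce)
  stopifnot(n >= 1)
  ranges <- ranges[param_names()]
  if (any(vapply(ranges, is.null, logical(1)))) {
    stop("ranges must cover every parameter", call. = FALSE)
  }
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  if (any(lo < 0) || any(hi < lo)) {
    stop("ranges must be non-negative intervals", call. = FALSE)
  }
  if (ranges$alpha[1] < 0 || ranges$alpha[2] > 1) {
    stop("alpha range must lie within [0, 1]", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  accepted <- vector("list", n)
  n_acc <- 0L
  n_drawn <- 0L
  chunk <- max(1024L, 4L * n)
  while (n_acc < n) {
    m <- matrix(stats::runif(chunk * 21L), nrow = chunk)
    cand <- sweep(sweep(m, 2L, hi - lo, `*`), 2L, lo, `+`)
    colnames(cand) <- param_names()
    n_drawn <- n_drawn + chunk
    # vectorized constraint screen (ranges already enforce non-negativity
    # and the alpha range)
    ok <- cand[, "V2"] > cand[, "V1"] + eps &
      cand[, "W2"] > cand[, "W1"] + eps &
      cand[, "P1"] > cand[, "P2"] + eps &
      cand[, "D"] > cand[, "E"] + eps &
      cand[, "H4"] > cand[, "H5"] + eps &
      cand[, "T"] > cand[, "H4"] + eps
    if (enforce != "none") {
      a <- cand[, "alpha"]
      ok1 <- a * cand[, "W2"] - a * cand[, "H2"] < 0 &
        cand[, "H5"] - cand[, "H4"] - cand[, "B"] + cand[, "K2"] +
          cand[, "R2"] < 0
      ok2 <- cand[, "A"] - cand[, "K2"] < 0 &
        cand[, "H4"] - cand[, "H5"] - cand[, "R2"] < 0 &
        a * cand[, "W1"] - a * cand[, "P1"] - a * cand[, "H2"] < 0
      ok <- ok & switch(enforce,
                        condition1 = ok1,
                        condition2 = ok2,
                        both = ok1 & ok2)
    }
    for (i in which(ok)) {
      if (n_acc >= n) break
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- structure(cand[i, ], class = "game_params")
    }
    if (n_drawn >= max_draws && (n_acc / n_drawn) < floor) {
      stop("scenario generation failed: acceptance rate ",
           signif(n_acc / n_drawn, 3), " below floor ", floor,
           " after ", n_drawn, " draws (infeasible ranges/conditions?)",
           call. = FALSE)
    }
    if (n_drawn >= 50 * max_draws && n_acc < n) {
      stop("scenario generation failed: draw budget exhausted", call. = FALSE)
    }
  }
  structure(list(params = accepted, seed = as.integer(seed),
                 ranges = ranges, enforce = enforce,
                 acceptance_rate = n_acc / n_drawn),
            class = "scenario_batch")
}

#' @export
print.scenario_batch <- function(x, ...) {
  cat("Scenario batch: ", length(x$params), " parameter sets (seed ",
      x$seed, ", enforce = ", x$enforce, ", acceptance rate ",
      signif(x$acceptance_rate, 3), ")\n", sep = "")
  invisible(x)
}
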