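# Payoff matrix of the tripartite game and expected payoffs under mixed
# strategies.  The eight-profile table is the single source of truth: the
# replicator field has an independent closed form in dynamics.R, and their
# agreement is a cross-check, not a definition.

#' Enumerate the eight pure strategy profiles
#'
#' Fixed enumeration order: allocator (GNPO) slowest, then hospital, then
#' government, matching the payoff table's row/column layout so serialized
#' tables are stable.
#'
#' @return Data frame with columns `gnpo`, `hospital`, `government` (8 rows).
#' @export
strategy_profiles <- function() {
  out <- expand.grid(
    government = c("strict", "loose"),
    hospital = c("accept", "refuse"),
    gnpo = c("able", "unable"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[, c("gnpo", "hospital", "government")]
}

#' Build the eight-profile payoff table
#'
#' Evaluates the per-player payoffs of every pure strategy profile at a
#' parameter set.  Strategies: the allocator is `"able"`/`"unable"` to
#' allocate on demand, the hospital `"accept"`s or `"refuse"`s-and-fights,
#' the government supervises `"strict"`ly or `"loose"`ly.
#'
#' @param p A valid `"game_params"` vector.
#' @return Data frame of class `"payoff_table"`: profile columns plus
#'   `u_gnpo`, `u_hospital`, `u_government` (payoff units).
#' @examples
#' pt <- payoff_table(baseline_params())
#' subset(pt, gnpo == "able" & hospital == "accept" & government == "strict")
#' @export
payoff_table <- function(p) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  .stop_if_invalid(p, strict = FALSE)
  a <- p[["alpha"]]
  cells <- list(
    # able, accept
    able.accept.strict   = c(0, -p[["E"]], p[["R1"]] + p[["R2"]] - p[["H4"]]),
    able.accept.loose    = c(0, -p[["E"]], p[["R1"]] - p[["H5"]]),
    # able, refuse-and-fight
    able.refuse.strict   = c(-p[["K1"]] - a * p[["V1"]] - a * p[["H1"]],
                             a * p[["W1"]] - p[["E"]] - a * p[["P1"]] - a * p[["H2"]],
                             p[["R1"]] + p[["R2"]] + p[["K1"]] + a * p[["P1"]] - p[["H4"]]),
    able.refuse.loose    = c(-a * p[["V1"]] - a * p[["H1"]],
                             a * p[["W1"]] - p[["E"]] - a * p[["H2"]],
                             p[["R1"]] - p[["H5"]] - p[["T"]]),
    # unable, accept
    unable.accept.strict = c(p[["A"]] - p[["K2"]],
                             p[["B"]] - p[["D"]],
                             p[["R2"]] + p[["K2"]] - p[["B"]] - p[["H3"]] - p[["H4"]]),
    unable.accept.loose  = c(p[["A"]], -p[["D"]], -p[["H3"]] - p[["H5"]]),
    # unable, refuse-and-fight
    unable.refuse.strict = c(p[["A"]] - a * p[["V2"]] - a * p[["H1"]] - p[["K1"]] - p[["K2"]],
                             a * p[["W2"]] - p[["D"]] - a * p[["P2"]] - a * p[["H2"]],
                             p[["R2"]] + p[["K1"]] + p[["K2"]] + a * p[["P2"]] - p[["H3"]] - p[["H4"]]),
    unable.refuse.loose  = c(p[["A"]] - a * p[["V2"]] - a * p[["H1"]],
                             a * p[["W2"]] - p[["D"]] - a * p[["H2"]],
                             -p[["H3"]] - p[["H5"]] - p[["T"]])
  )
  prof <- strategy_profiles()
  key <- paste(prof$gnpo, prof$hospital, prof$government, sep = ".")
  u <- t(vapply(cells[key], identity, numeric(3)))
  out <- cbind(prof, data.frame(u_gnpo = u[, 1], u_hospital = u[, 2],
                                u_government = u[, 3]))
  rownames(out) <- NULL
  class(out) <- c("payoff_table", "data.frame")
  attr(out, "params") <- p
  out
}

#' Write a payoff table as CSV
#'
#' Columns: `profile` (dot-joined strategies), `u_gnpo`, `u_hospital`,
#' `u_government`.
#'
#' @param pt A `"payoff_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_payoff_csv <- function(pt, path) {
  stopifnot(inherits(pt, "payoff_table"))
  out <- data.frame(
    profile = paste(pt$gnpo, pt$hospital, pt$government, sep = "."),
    u_gnpo = pt$u_gnpo, u_hospital = pt$u_hospital,
    u_government = pt$u_government)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.check_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("state must be (x, y, z) within the unit cube", call. = FALSE)
  }
  names(s) <- c("x", "y", "z")
  s
}

#' Expected payoffs under a mixed-strategy state
#'
#' Given the population state `s = (x, y, z)` — the probabilities of
#' on-demand allocation, acceptance, and strict supervision — computes each
#' player's expected payoff for either pure strategy and the mixture
#' average, by probability-weighting the payoff table over the opponents'
#' mixtures.
#'
#' @param p A valid `"game_params"` vector.
#' @param s Numeric state `(x, y, z)` in the unit cube.
#' @return List with `E11`, `E12`, `E1` (allocator: able / unable /
#'   average), `E21`, `E22`, `E2` (hospital: accept / refuse / average),
#'   `E31`, `E32`, `E3` (government: strict / loose / average).
#' @examples
#' expected_payoffs(baseline_params(), c(1, 1, 1))$E12  # A - K2
#' @export
expected_payoffs <- function(p, s) {
  pt <- payoff_table(p)
  s <- .check_state(s)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  wg <- ifelse(pt$gnpo == "able", x, 1 - x)
  wh <- ifelse(pt$hospital == "accept", y, 1 - y)
  ws <- ifelse(pt$government == "strict", z, 1 - z)

  E11 <- sum((wh * ws * pt$u_gnpo)[pt$gnpo == "able"])
  E12 <- sum((wh * ws * pt$u_gnpo)[pt$gnpo == "unable"])
  E21 <- sum((wg * ws * pt$u_hospital)[pt$hospital == "accept"])
  E22 <- sum((wg * ws * pt$u_hospital)[pt$hospital == "refuse"])
  E31 <- sum((wg * wh * pt$u_government)[pt$government == "strict"])
  E32 <- sum((wg * wh * pt$u_government)[pt$government == "loose"])

  list(E11 = E11, E12 = E12, E1 = x * E11 + (1 - x) * E12,
       E21 = E21, E22 = E22, E2 = y * E21 + (1 - y) * E22,
       E31 = E31, E32 = E32, E3 = z * E31 + (1 - z) * E32)
}
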