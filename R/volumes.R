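# Strategy-preference volumes: the share of the strategy cube lying on the
# attracting side of each player's threshold surface, read as the
# probability of evolving toward the corresponding pure strategy.
#
# Two conventions are implemented for the allocator volume: the unclipped
# closed form/integral (which integrates the threshold without clipping and
# can exceed the cube), and a geometric variant with the surface clipped
# into [0, 1] so the result is a genuine probability.  The hospital and
# government integrands are unbounded at denominator roots for realistic
# parameters, so only the clipped convention is defined for them.

.midpoints <- function(n) (seq_len(n) - 0.5) / n

#' Closed-form allocator preference volume
#'
#' `V_G1 = (A - K2)(A - K2 + 2 alpha V1 - 2 alpha V2) / (2 alpha K2 (V2 - V1))`
#' — the closed-form evaluation of the integral of the unclipped threshold
#' `y*(z)` over `z` from `A/K2` to 1.
#'
#' @param p A valid `"game_params"` vector.
#' @return Numeric scalar.
#' @examples
#' v_g1_closed(baseline_params())  # 3325/3600
#' @export
v_g1_closed <- function(p) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  a <- p[["alpha"]]
  den <- 2 * a * p[["K2"]] * (p[["V2"]] - p[["V1"]])
  if (den == 0) {
    stop("v_g1_closed undefined: alpha, K2 and V2 - V1 must be nonzero",
         call. = FALSE)
  }
  u <- p[["A"]] - p[["K2"]]
  u * (u + 2 * a * p[["V1"]] - 2 * a * p[["V2"]]) / den
}

#' Quadrature of the unclipped allocator volume integral
#'
#' Midpoint-rule evaluation of the integral of the unclipped threshold
#' `y*(z)` over `z` in \[A/K2, 1\] (the x-integration is trivial).  Used as
#' an independent check of [v_g1_closed()].
#'
#' @param p A valid `"game_params"` vector.
#' @param n Number of midpoint cells.
#' @return Numeric scalar (signed if `A/K2 > 1`).
#' @export
v_g1_integral <- function(p, n = 2001) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  th <- thresholds(p)
  lo <- p[["A"]] / p[["K2"]]
  z <- lo + .midpoints(n) * (1 - lo)
  mean(th$y_star(z)) * (1 - lo)
}

#' Clipped (geometric) strategy-preference volume
#'
#' Volume of the region of the unit cube on the attracting side of a
#' player's threshold surface, with the surface value clipped into
#' \[0, 1\] pointwise before integration, so the result is a probability:
#' \describe{
#'   \item{`"G"`}{allocator: share of the cube with `y < y*(z)` (drift
#'     toward on-demand allocation).}
#'   \item{`"Q"`}{hospital: share with `x < x*(z)` (drift toward
#'     refuse-and-fight).}
#'   \item{`"N"`}{government: share with `y < y**(x)` (drift toward strict
#'     supervision).}
#' }
#' Each preference-volume double integral has one trivial axis, so a 1-D midpoint
#' rule along the non-trivial axis with `n` cells is exactly the 2-D grid
#' value.  Clipping removes the singular cells at denominator roots;
#' arguments hitting a root exactly are recorded in the `"singular"`
#' attribute and treated by the clip (limit value 0 or 1 from either side).
#'
#' @param p A valid `"game_params"` vector.
#' @param which `"G"`, `"Q"`, or `"N"`.
#' @param n Number of quadrature cells (default 2001).
#' @return Numeric scalar in \[0, 1\], with attribute `"singular"` giving
#'   the number of grid points where the threshold denominator vanished.
#' @examples
#' v_clipped(baseline_params(), "G")  # 119/144
#' @export
v_clipped <- function(p, which = c("G", "Q", "N"), n = 2001) {
  which <- match.arg(which)
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  th <- thresholds(p)
  t_ax <- .midpoints(n)
  f <- switch(which, G = th$y_star, Q = th$x_star, N = th$y_double_star)
  vals <- f(t_ax)
  n_sing <- sum(is.nan(vals))
  # at an exact pole the clipped integrand's two one-sided limits are 0 and
  # 1; a single midpoint there gets weight 1/n -> use 1/2, vanishing with n
  vals[is.nan(vals)] <- 0.5
  out <- mean(pmin(pmax(vals, 0), 1))
  attr(out, "singular") <- n_sing
  out
}

#' Hospital refuse-and-fight volume (clipped quadrature)
#'
#' @inheritParams v_clipped
#' @return Numeric scalar in \[0, 1\].
#' @export
v_q1 <- function(p, n = 2001) v_clipped(p, "Q", n)

#' Government strict-supervision volume (clipped quadrature)
#'
#' @inheritParams v_clipped
#' @return Numeric scalar in \[0, 1\].
#' @export
v_n1 <- function(p, n = 2001) v_clipped(p, "N", n)

#' Full strategy-preference volume report
#'
#' Computes all six volumes: the allocator volume in both the unclipped
#' convention (closed form and its own quadrature) and the clipped
#' geometric convention, and the clipped hospital and government volumes,
#' with the complementary volumes by the partition identity `V_2 = 1 -
#' V_1`.
#'
#' @param p A valid `"game_params"` vector.
#' @param n Quadrature cells per axis.
#' @return List of class `"volume_report"`.
#' @export
volume_report <- function(p, n = 2001) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  .stop_if_invalid(p, strict = FALSE)
  vg_closed <- v_g1_closed(p)
  vg_quad <- v_g1_integral(p, n)
  vg_clip <- v_clipped(p, "G", n)
  vq <- v_clipped(p, "Q", n)
  vn <- v_clipped(p, "N", n)
  structure(list(
    V_G1 = vg_closed, V_G1_integral = vg_quad,
    V_G1_clipped = as.numeric(vg_clip), V_G2 = 1 - vg_closed,
    V_G2_clipped = 1 - as.numeric(vg_clip),
    V_Q1 = as.numeric(vq), V_Q2 = 1 - as.numeric(vq),
    V_N1 = as.numeric(vn), V_N2 = 1 - as.numeric(vn),
    grid = n,
    singular_cells = c(G = attr(vg_clip, "singular"),
                       Q = attr(vq, "singular"),
                       N = attr(vn, "singular"))),
    class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("Strategy-preference volumes (grid ", x$grid, "):\n", sep = "")
  cat(sprintf("  allocator   V_G1 = %.6f (unclipped; quadrature %.6f), clipped %.6f\n",
              x$V_G1, x$V_G1_integral, x$V_G1_clipped))
  cat(sprintf("  hospital    V_Q1 = %.6f (refuse-and-fight), V_Q2 = %.6f\n",
              x$V_Q1, x$V_Q2))
  cat(sprintf("  government  V_N1 = %.6f (strict), V_N2 = %.6f\n",
              x$V_N1, x$V_N2))
  invisible(x)
}

#' Export a volume report (with derivative signs) as JSON
#'
#' @param p A valid `"game_params"` vector.
#' @param path Output path.
#' @param n Quadrature cells.
#' @return `path`, invisibly.
#' @export
write_volumes_json <- function(p, path, n = 2001) {
  vr <- volume_report(p, n)
  st <- inference_signs(p, n = n)
  obj <- c(unclass(vr)[c("V_G1", "V_G1_integral", "V_G1_clipped", "V_G2",
                         "V_Q1", "V_Q2", "V_N1", "V_N2")],
           list(grid = vr$grid,
                signs = lapply(seq_len(nrow(st)), function(i) {
                  list(volume = st$volume[i], parameter = st$parameter[i],
                       derivative = st$derivative[i], sign = st$sign[i])
                })))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.central_diff <- function(fn, p, param, delta) {
  h <- delta * max(abs(p[[param]]), 1)
  p_up <- p; p_up[[param]] <- p[[param]] + h
  p_dn <- p; p_dn[[param]] <- p[[param]] - h
  (fn(p_up) - fn(p_dn)) / (2 * h)
}

#' Sensitivity signs of the strategy-preference volumes
#'
#' Central-difference partial derivatives of the volume functions with
#' respect to the policy levers they respond to: the allocator volume
#' w.r.t. `alpha`, `K2`, `A` (both the unclipped closed form and the
#' clipped geometric volume are differentiated, since their signs can
#' disagree); the hospital refuse-and-fight volume w.r.t. `B`, `P1`, `P2`;
#' the government strict-supervision volume w.r.t. `K2`, `T`, `P2`, `B`.
#'
#' Quadrature volumes carry discretization noise; a derivative whose
#' magnitude is below 10x the estimated quadrature noise is reported with
#' sign `"indeterminate"` rather than guessed.
#'
#' @param p A valid `"game_params"` vector.
#' @param delta Relative step for the central differences.
#' @param n Quadrature cells used for the finite differences.  The volumes
#'   can be step-like in the swept parameter (a clipped threshold moves a
#'   jump location), so resolving a step `delta` needs a grid much finer
#'   than for the volumes themselves; the default is a fine 1-D grid that
#'   is still cheap.
#' @return Data frame with columns `volume`, `parameter`, `derivative`,
#'   `sign` (`"+"`, `"-"`, `"0"`, or `"indeterminate"`).
#' @examples
#' inference_signs(baseline_params())
#' @export
inference_signs <- function(p, delta = 1e-4, n = 2000001) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  rows <- list()
  add <- function(volume, param, fn, noise) {
    d <- .central_diff(fn, p, param, delta)
    h <- delta * max(abs(p[[param]]), 1)
    thresh <- 10 * noise / (2 * h)
    sgn <- if (abs(d) <= max(thresh, 1e-12)) {
      if (noise > 0) "indeterminate" else "0"
    } else if (d > 0) "+" else "-"
    rows[[length(rows) + 1L]] <<- data.frame(
      volume = volume, parameter = param, derivative = d, sign = sgn)
  }
  # quadrature noise estimate: change under grid refinement
  noise_for <- function(fn_n) abs(fn_n(n) - fn_n(max(2L, n %/% 2L) + 1L))
  gq_noise <- noise_for(function(k) as.numeric(v_clipped(p, "G", k)))
  qq_noise <- noise_for(function(k) as.numeric(v_clipped(p, "Q", k)))
  nq_noise <- noise_for(function(k) as.numeric(v_clipped(p, "N", k)))

  for (param in c("alpha", "K2", "A")) {
    add("V_G1_closed", param, v_g1_closed, 0)
    add("V_G1_clipped", param,
        function(q) as.numeric(v_clipped(q, "G", n)), gq_noise)
  }
  for (param in c("B", "P1", "P2")) {
    add("V_Q1", param, function(q) as.numeric(v_clipped(q, "Q", n)), qq_noise)
  }
  for (param in c("K2", "T", "P2", "B")) {
    add("V_N1", param, function(q) as.numeric(v_clipped(q, "N", n)), nq_noise)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
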