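# Equilibrium enumeration and Lyapunov (indirect-method) stability
# classification.  At the cube corners the Jacobian's off-diagonal entries
# vanish, so the eigenvalues have exact closed forms in the parameters;
# numeric eigendecomposition of the analytic Jacobian is the cross-check.

#' The eight pure-strategy equilibria
#'
#' Every corner of the strategy cube is a rest point of the replicator
#' system; in this asymmetric game only pure profiles can be evolutionarily
#' stable, so these are the candidate equilibria.
#'
#' @return 8 x 3 numeric matrix, rows `E1`..`E8` in the conventional order
#'   E1(0,0,0), E2(1,0,0), E3(0,1,0), E4(0,0,1), E5(1,1,0), E6(1,0,1),
#'   E7(0,1,1), E8(1,1,1); columns `x`, `y`, `z`.
#' @export
pure_equilibria <- function() {
  m <- rbind(E1 = c(0, 0, 0), E2 = c(1, 0, 0), E3 = c(0, 1, 0),
             E4 = c(0, 0, 1), E5 = c(1, 1, 0), E6 = c(1, 0, 1),
             E7 = c(0, 1, 1), E8 = c(1, 1, 1))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Analytic Jacobian of the replicator field
#'
#' The 3 x 3 matrix of partial derivatives of the replicator equations with
#' respect to `(x, y, z)`, in closed form.  Matches a central
#' finite-difference Jacobian of [replicator_field()] at interior states.
#'
#' @param p A valid `"game_params"` vector.
#' @param s State `(x, y, z)` in the unit cube.
#' @return 3 x 3 numeric matrix.
#' @export
replicator_jacobian <- function(p, s) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  s <- .check_state(s)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  a <- p[["alpha"]]
  gx <- .bracket_x(p, y, z)
  gy <- .bracket_y(p, x, z)
  gz <- .bracket_z(p, x, y)
  a11 <- (1 - 2 * x) * gx
  a12 <- x * (1 - x) * (a * p[["V1"]] - a * p[["V2"]])
  a13 <- x * (1 - x) * p[["K2"]]
  a21 <- y * (1 - y) * (z * (a * p[["P1"]] - a * p[["P2"]] - p[["B"]]) +
                          a * p[["W2"]] - a * p[["W1"]])
  a22 <- (1 - 2 * y) * gy
  a23 <- y * (1 - y) * (x * a * p[["P1"]] - x * a * p[["P2"]] - x * p[["B"]] +
                          p[["B"]] + a * p[["P2"]])
  a31 <- z * (1 - z) * (a * p[["P1"]] - a * p[["P2"]] - p[["K2"]] +
                          y * (p[["B"]] - a * p[["P1"]] + a * p[["P2"]]))
  a32 <- z * (1 - z) * (-p[["B"]] - a * p[["P2"]] - p[["K1"]] - p[["T"]] +
                          x * (p[["B"]] - a * p[["P1"]] + a * p[["P2"]]))
  a33 <- (1 - 2 * z) * gz
  matrix(c(a11, a12, a13, a21, a22, a23, a31, a32, a33),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("dx", "dy", "dz"), c("x", "y", "z")))
}

.corner_label <- function(point) {
  corners <- pure_equilibria()
  point <- as.numeric(point)
  if (length(point) != 3L || !all(point %in% c(0, 1))) {
    stop("point must be a corner of the unit cube", call. = FALSE)
  }
  rownames(corners)[apply(corners, 1L, function(r) all(r == point))]
}

#' Closed-form eigenvalues at a corner equilibrium
#'
#' At a corner the Jacobian is diagonal, so the eigenvalues are
#' `((1-2x) gx, (1-2y) gy, (1-2z) gz)` — exact expressions in the
#' parameters (e.g. at E8(1,1,1): `A - K2`, `alpha W1 - alpha P1 - alpha
#' H2`, `H4 - H5 - R2`).  These equal the numeric eigenvalues of
#' [replicator_jacobian()] at the corner.
#'
#' @param p A valid `"game_params"` vector.
#' @param point A corner of the unit cube (each coordinate 0 or 1), or a
#'   corner label `"E1"`..`"E8"`.
#' @return Named numeric vector `c(lambda_x, lambda_y, lambda_z)` (the
#'   growth rates of perturbations in the x-, y- and z-directions).
#' @examples
#' corner_eigenvalues(baseline_params(), "E3")  # (-25, -6, -10)
#' @export
corner_eigenvalues <- function(p, point) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  if (is.character(point)) {
    corners <- pure_equilibria()
    if (!point %in% rownames(corners)) {
      stop("unknown corner label '", point, "'", call. = FALSE)
    }
    point <- corners[point, ]
  }
  point <- as.numeric(point)
  .corner_label(point)  # validates
  x <- point[1]; y <- point[2]; z <- point[3]
  c(lambda_x = (1 - 2 * x) * .bracket_x(p, y, z),
    lambda_y = (1 - 2 * y) * .bracket_y(p, x, z),
    lambda_z = (1 - 2 * z) * .bracket_z(p, x, y))
}

#' Check the two stability condition sets
#'
#' Condition set 1 (stability of the corner E3 = not-on-demand/accept/
#' loose): `alpha W2 - alpha H2 < 0` and `H5 - H4 - B + K2 + R2 < 0`.
#' Condition set 2 (stability of E8 = on-demand/accept/strict):
#' `A - K2 < 0`, `H4 - H5 - R2 < 0`, `alpha W1 - alpha P1 - alpha H2 < 0`.
#' (`-A < 0` of E3 holds automatically for positive A.)
#'
#' @param p A valid `"game_params"` vector.
#' @return Data frame of class `"condition_check"`: columns `condition`
#'   (1 or 2), `inequality`, `value`, `satisfied`; attributes `condition1`,
#'   `condition2`, `both` give the per-set conjunctions.
#' @examples
#' check_ess_conditions(baseline_params())
#' @export
check_ess_conditions <- function(p) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  a <- p[["alpha"]]
  vals <- c(
    a * p[["W2"]] - a * p[["H2"]],
    p[["H5"]] - p[["H4"]] - p[["B"]] + p[["K2"]] + p[["R2"]],
    p[["A"]] - p[["K2"]],
    p[["H4"]] - p[["H5"]] - p[["R2"]],
    a * p[["W1"]] - a * p[["P1"]] - a * p[["H2"]])
  out <- data.frame(
    condition = c(1L, 1L, 2L, 2L, 2L),
    inequality = c("alpha*W2 - alpha*H2 < 0",
                   "H5 - H4 - B + K2 + R2 < 0",
                   "A - K2 < 0",
                   "H4 - H5 - R2 < 0",
                   "alpha*W1 - alpha*P1 - alpha*H2 < 0"),
    value = vals,
    satisfied = vals < 0)
  class(out) <- c("condition_check", "data.frame")
  attr(out, "condition1") <- all(out$satisfied[out$condition == 1L])
  attr(out, "condition2") <- all(out$satisfied[out$condition == 2L])
  attr(out, "both") <- attr(out, "condition1") && attr(out, "condition2")
  out
}

#' @export
print.condition_check <- function(x, ...) {
  cat("Stability condition sets: condition 1 ",
      if (attr(x, "condition1")) "satisfied" else "violated",
      ", condition 2 ",
      if (attr(x, "condition2")) "satisfied" else "violated", "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Detect interior (fully mixed) rest points
#'
#' Solves the three replicator brackets for a common root in the open cube.
#' On the allocator and hospital null surfaces `y = y*(z)` and `x = x*(z)`,
#' the government bracket reduces to a single function of `z`, whose sign
#' changes are bracketed on a grid and refined by root finding.  Interior
#' rest points are reported for completeness only: in an asymmetric game a
#' mixed-strategy equilibrium is never evolutionarily stable, so they are
#' never classified as ESS.
#'
#' @param p A valid `"game_params"` vector.
#' @param n_grid Scan resolution in `z`.
#' @return Matrix with columns `x`, `y`, `z` (possibly 0 rows).
#' @export
interior_equilibria <- function(p, n_grid = 2001) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  th <- thresholds(p)
  h <- function(z) {
    x <- th$x_star(z); y <- th$y_star(z)
    ifelse(is.nan(x) | is.nan(y) | x <= 0 | x >= 1 | y <= 0 | y >= 1,
           NA_real_, .bracket_z(p, x, y))
  }
  zs <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  hv <- vapply(zs, h, numeric(1))
  roots <- list()
  for (i in seq_len(n_grid - 1L)) {
    if (is.na(hv[i]) || is.na(hv[i + 1L])) next
    if (hv[i] == 0) {
      roots[[length(roots) + 1L]] <- zs[i]
    } else if (hv[i] * hv[i + 1L] < 0) {
      r <- stats::uniroot(h, c(zs[i], zs[i + 1L]), tol = 1e-12)
      roots[[length(roots) + 1L]] <- r$root
    }
  }
  if (!length(roots)) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  z <- unlist(roots)
  out <- cbind(x = th$x_star(z), y = th$y_star(z), z = z)
  out[!duplicated(round(out, 9)), , drop = FALSE]
}

#' Classify the corner equilibria by the Lyapunov indirect method
#'
#' Evaluates the closed-form eigenvalues at each corner and applies the
#' indirect-method rule: all real parts below `-eps` gives an
#' asymptotically stable point (ESS); any real part above `+eps` gives an
#' unstable point; otherwise the point is critical and the linearization is
#' inconclusive (the class is reported as `"critical"`, never guessed).
#'
#' @param p A valid `"game_params"` vector.
#' @param eps Half-width of the zero band on eigenvalue real parts.
#' @param interior If `TRUE`, also detect interior rest points (reported in
#'   the `interior` attribute, never classified as ESS).
#' @return Data frame of class `"equilibrium_report"`: columns `point`,
#'   `x`, `y`, `z`, `lambda_x`, `lambda_y`, `lambda_z`, `class`.
#'   Attributes: `conditions` (the [check_ess_conditions()] table),
#'   `interior` (matrix of interior rest points if requested).
#' @examples
#' classify_equilibria(baseline_params())
#' @export
classify_equilibria <- function(p, eps = 1e-9, interior = FALSE) {
  if (!inherits(p, "game_params")) p <- game_params(.values = p)
  .stop_if_invalid(p, strict = FALSE)
  corners <- pure_equilibria()
  rows <- lapply(rownames(corners), function(lbl) {
    ev <- corner_eigenvalues(p, corners[lbl, ])
    cls <- if (all(ev < -eps)) "ESS"
           else if (any(ev > eps)) "unstable"
           else "critical"
    data.frame(point = lbl, x = corners[lbl, 1], y = corners[lbl, 2],
               z = corners[lbl, 3], lambda_x = ev[["lambda_x"]],
               lambda_y = ev[["lambda_y"]], lambda_z = ev[["lambda_z"]],
               class = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("equilibrium_report", "data.frame")
  attr(out, "conditions") <- check_ess_conditions(p)
  if (interior) attr(out, "interior") <- interior_equilibria(p)
  out
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Corner equilibria (Lyapunov indirect method):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  ess <- x$point[x$class == "ESS"]
  cat("ESS: ", if (length(ess)) paste(ess, collapse = ", ") else "none",
      "\n", sep = "")
  inter <- attr(x, "interior")
  if (!is.null(inter) && nrow(inter)) {
    cat("Interior rest points detected (never ESS in an asymmetric game):\n")
    print(round(inter, 6))
  }
  invisible(x)
}

#' Export a stability report as JSON
#'
#' Writes per-corner records (point, eigenvalues, class) plus the
#' stability-condition block.
#'
#' @param rep An `"equilibrium_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(rep, path) {
  stopifnot(inherits(rep, "equilibrium_report"))
  cond <- attr(rep, "conditions")
  obj <- list(
    equilibria = lapply(seq_len(nrow(rep)), function(i) {
      list(point = rep$point[i],
           state = c(rep$x[i], rep$y[i], rep$z[i]),
           eigenvalues = c(rep$lambda_x[i], rep$lambda_y[i], rep$lambda_z[i]),
           class = rep$class[i])
    }),
    conditions = list(
      condition1 = attr(cond, "condition1"),
      condition2 = attr(cond, "condition2"),
      checks = lapply(seq_len(nrow(cond)), function(i) {
        list(condition = cond$condition[i], inequality = cond$inequality[i],
             value = cond$value[i], satisfied = cond$satisfied[i])
      })))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
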