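# Parameter-sensitivity sweeps: replicator trajectories over printed
# parameter grids, with deterministic CSV/JSON reporting.

#' Define a parameter sweep
#'
#' @param param Name of the swept parameter.
#' @param values Numeric grid of values.
#' @param base Base parameter set the sweep perturbs.
#' @param init Initial state, or a matrix/list of initial states (rows
#'   `(x, y, z)`).
#' @param horizon Integration horizon per run.
#' @param field_tol Convergence threshold on the field norm.
#' @return List of class `"sweep_spec"`.
#' @export
sweep_spec <- function(param, values, base = baseline_params(),
                       init = c(0.5, 0.5, 0.5), horizon = 50,
                       field_tol = 1e-8) {
  stopifnot(param %in% param_names(), length(values) >= 1)
  if (!inherits(base, "game_params")) base <- game_params(.values = base)
  if (is.numeric(init) && is.null(dim(init))) init <- matrix(init, nrow = 1)
  if (is.list(init)) init <- do.call(rbind, init)
  colnames(init) <- c("x", "y", "z")
  structure(list(param = param, values = as.numeric(values), base = base,
                 init = init, horizon = horizon, field_tol = field_tol),
            class = "sweep_spec")
}

#' Interior lattice of initial states
#'
#' The 27 points of \{0.25, 0.5, 0.75\}^3, used to probe basin structure
#' when a single symmetric start is not enough.
#'
#' @return 27 x 3 matrix.
#' @export
init_lattice <- function() {
  g <- c(0.25, 0.5, 0.75)
  m <- as.matrix(expand.grid(x = g, y = g, z = g))
  rownames(m) <- NULL
  m
}

#' The nine preset sensitivity sweeps
#'
#' Grids over the baseline: `alpha` 0.1–0.9 (step 0.1); `H2` 80, 95, 110,
#' 125, 140; `H4` 70, 85, 100, 115, 130; `H5` 30, 40, 50, 60, 70; `T` 100,
#' 125, 150, 175, 200; `K1` 40, 60, 80, 100, 120; `B` 40, 60, 80, 100,
#' 120; `P1` 120, 140, 160, 180, 200; `A` 10, 15, 20, 25, 30, 35, 40.
#'
#' @inheritParams sweep_spec
#' @return Named list of nine `"sweep_spec"` objects.
#' @export
preset_sweeps <- function(base = baseline_params(), init = c(0.5, 0.5, 0.5),
                          horizon = 50) {
  grids <- list(
    alpha = seq(0.1, 0.9, by = 0.1),
    H2 = c(80, 95, 110, 125, 140),
    H4 = c(70, 85, 100, 115, 130),
    H5 = c(30, 40, 50, 60, 70),
    T = c(100, 125, 150, 175, 200),
    K1 = c(40, 60, 80, 100, 120),
    B = c(40, 60, 80, 100, 120),
    P1 = c(120, 140, 160, 180, 200),
    A = c(10, 15, 20, 25, 30, 35, 40))
  out <- lapply(names(grids), function(k) {
    sweep_spec(k, grids[[k]], base = base, init = init, horizon = horizon)
  })
  names(out) <- names(grids)
  out
}

#' Run a parameter sweep
#'
#' Integrates the replicator system for every value of the grid (and every
#' initial state of the spec).  Each derived parameter set is validated
#' with ties on the order constraints allowed (`strict = FALSE`), because
#' printed grids may touch a boundary (e.g. an accountability loss equal to
#' the strict-supervision cost); genuine violations are recorded as
#' per-value errors without aborting the batch.  Runs are deterministic:
#' there is no randomness in the ODE solves.
#'
#' @param spec A `"sweep_spec"`.
#' @return List of class `"sweep_result"`: `spec`, `runs` (per value: list
#'   of trajectories or an error record), and `summary` (data frame with,
#'   per value and start, terminal and time-averaged `x`, `y`, `z`, the
#'   convergence flag, and the terminal corner and its stability class
#'   under the swept parameter set).
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  runs <- vector("list", length(spec$values))
  names(runs) <- as.character(spec$values)
  summ <- list()
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    pv <- spec$base
    pv[[spec$param]] <- v
    rep <- validate_params(pv, strict = FALSE)
    if (!attr(rep, "valid")) {
      bad <- rep$constraint[!rep$satisfied]
      runs[[i]] <- list(error = paste0("value ", v, " violates: ",
                                       paste(bad, collapse = ", ")))
      next
    }
    ess <- classify_equilibria(pv)
    trajs <- vector("list", nrow(spec$init))
    for (j in seq_len(nrow(spec$init))) {
      tr <- integrate_game(pv, s0 = spec$init[j, ], horizon = spec$horizon,
                           field_tol = spec$field_tol)
      trajs[[j]] <- tr
      corner_class <- if (!is.na(tr$terminal_corner)) {
        ess$class[ess$point == tr$terminal_corner]
      } else NA_character_
      # time-average by trapezoid over the recorded grid
      tavg <- function(v) {
        t <- tr$states$t
        sum(diff(t) * (v[-length(v)] + v[-1]) / 2) / (max(t) - min(t))
      }
      summ[[length(summ) + 1L]] <- data.frame(
        param = spec$param, value = v,
        x0 = spec$init[j, 1], y0 = spec$init[j, 2], z0 = spec$init[j, 3],
        x_end = tr$terminal[["x"]], y_end = tr$terminal[["y"]],
        z_end = tr$terminal[["z"]],
        x_mean = tavg(tr$states$x), y_mean = tavg(tr$states$y),
        z_mean = tavg(tr$states$z),
        converged = tr$converged,
        terminal_corner = tr$terminal_corner,
        corner_class = corner_class)
    }
    runs[[i]] <- trajs
  }
  structure(list(spec = spec,
                 runs = runs,
                 summary = if (length(summ)) do.call(rbind, summ)
                           else data.frame()),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep of ", x$spec$param, " over {",
      paste(x$spec$values, collapse = ", "), "}\n", sep = "")
  if (nrow(x$summary)) {
    print.data.frame(x$summary[, c("value", "x_end", "y_end", "z_end",
                                   "converged", "terminal_corner")],
                     row.names = FALSE, digits = 4)
  }
  errs <- vapply(x$runs, function(r) !is.null(r$error), logical(1))
  if (any(errs)) {
    for (i in which(errs)) cat("  skipped: ", x$runs[[i]]$error, "\n")
  }
  invisible(x)
}

#' Write sweep results to disk
#'
#' One trajectory CSV per sweep (columns `value`, `start`, `t`, `x`, `y`,
#' `z`) plus a single JSON summary across sweeps.  Output is deterministic:
#' re-running produces byte-identical files.
#'
#' @param results A `"sweep_result"` or (possibly empty) list of them.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_sweep_results <- function(results, dir) {
  if (inherits(results, "sweep_result")) results <- list(results)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      stop("cannot create output directory '", dir, "'", call. = FALSE)
    }
  }
  files <- character(0)
  summaries <- list()
  for (res in results) {
    stopifnot(inherits(res, "sweep_result"))
    rows <- list()
    for (i in seq_along(res$runs)) {
      run <- res$runs[[i]]
      if (!is.null(run$error)) next
      for (j in seq_along(run)) {
        st <- run[[j]]$states
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(value = res$spec$values[i], start = j), st)
      }
    }
    csv <- file.path(dir, paste0("sweep_", res$spec$param, ".csv"))
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(value = numeric(0), start = integer(0), t = numeric(0),
                 x = numeric(0), y = numeric(0), z = numeric(0))
    utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
    files <- c(files, csv)
    summaries[[res$spec$param]] <- list(
      param = res$spec$param, values = res$spec$values,
      n_runs = sum(vapply(res$runs, function(r) is.null(r$error), logical(1))),
      errors = unlist(lapply(res$runs, function(r) r$error)),
      summary = res$summary)
  }
  js <- file.path(dir, "sweep_summary.json")
  jsonlite::write_json(summaries, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(c(files, js))
}

#' Plot sweep trajectories
#'
#' Base-graphics panel of one strategy share against time, one curve per
#' swept value (first initial state only).
#'
#' @param x A `"sweep_result"`.
#' @param coord Which share to plot: `"x"`, `"y"` or `"z"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, coord = c("z", "x", "y"), ...) {
  coord <- match.arg(coord)
  ok <- which(vapply(x$runs, function(r) is.null(r$error), logical(1)))
  if (!length(ok)) {
    warning("no successful runs to plot")
    return(invisible(x))
  }
  cols <- grDevices::hcl.colors(length(ok), "Dark 3")
  tmax <- max(vapply(ok, function(i) max(x$runs[[i]][[1]]$states$t),
                     numeric(1)))
  graphics::plot(NULL, xlim = c(0, tmax), ylim = c(0, 1),
                 xlab = "time", ylab = coord,
                 main = paste0("Sweep of ", x$spec$param), ...)
  for (k in seq_along(ok)) {
    st <- x$runs[[ok[k]]][[1]]$states
    graphics::lines(st$t, st[[coord]], col = cols[k], lty = 1)
  }
  graphics::legend("bottomright",
                   legend = paste(x$spec$param, "=", x$spec$values[ok]),
                   col = cols, lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
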