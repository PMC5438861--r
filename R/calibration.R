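# Bounded calibration of the estimated parameters: deterministic
# coarse-grid search over the bounded box followed by local refinement,
# with a sum-of-squared-relative-error loss against anchor observations.
#
# Free quantities may be plain parameter names (di, ci, se, dd, rd, sd, ...)
# or the derived knobs:
#   init_total   - the combined initiation rate di + ci (split equally),
#   cases_growth - the annual growth rate of the exogenous case series,
#   uptake_growth - the extrapolation rate of the uptake series.

#' Default calibration anchors
#'
#' The published values the model can be pinned to: persons in
#' rehabilitation in 2004 (4,563) and 2013 (7,195); the 2004 case load
#' (30,432); the case load in 2013 implied by scaling the 2004 base with
#' the national arrest growth factor 82,062/19,940 = 4.115; and the
#' reported order-of-magnitude relation that the abuser stock D runs at
#' about ten times the open case load L by the end of the historical
#' window (expressed as a ratio anchor D/L = 10 at 2014). The ratio anchor
#' is what identifies the initiation/self-conviction balance: the
#' rehabilitation and case-load trajectories alone carry no information
#' about `di`, `ci` or `se` (the L -> S -> R chain contains no C or D
#' term).
#'
#' @return Anchor `data.frame` with columns `year`, `stock`, `value`,
#'   `ref` (`NA` for a level anchor; a stock name for a ratio anchor
#'   `stock/ref = value`).
#' @export
default_calibration_anchors <- function() {
  data.frame(
    year = c(2004, 2013, 2004, 2013, 2014),
    stock = c("R", "R", "L", "L", "D"),
    value = c(4563, 7195, 30432, 30432 * (82062 / 19940), 10),
    ref = c(NA, NA, NA, NA, "L")
  )
}

#' Calibration problem
#'
#' @param free named list of `c(lower, upper)` bounds for each free
#'   quantity; names are parameter symbols or the derived knobs
#'   `init_total`, `cases_growth`, `uptake_growth`. `NULL` selects the
#'   default problem: `init_total` in \[0.10, 0.20\] (the combined range of
#'   `di` and `ci`), `se` in \[0.05, 0.10\] and `cases_growth` in
#'   \[0, 0.35\].
#' @param anchors anchor `data.frame` (`year`, `stock`, `value`, optional
#'   `ref`); default [default_calibration_anchors()]. Values must be
#'   positive; years must lie on the reporting grid.
#' @param grid simulation horizon for the loss evaluation; default
#'   2004-2014 monthly.
#' @param params baseline parameter set for the non-free parameters.
#' @param exo baseline exogenous flows; series growth knobs modify these.
#' @param state0 initial state.
#' @param grid_points coarse-search resolution per dimension (default 7).
#' @param seed accepted for interface uniformity; the search is
#'   deterministic and ignores it.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(free = NULL,
                                anchors = default_calibration_anchors(),
                                grid = time_grid(2004, 2014, 1 / 12),
                                params = sadcwc_params(),
                                exo = exogenous_flows(),
                                state0 = sadcwc_initial_state(),
                                grid_points = 7L, seed = 1L) {
  if (is.null(free)) {
    bd <- parameter_bounds()
    free <- list(init_total = bd$di + bd$ci,
                 se = bd$se,
                 cases_growth = c(0, 0.35))
  }
  stopifnot(is.list(free), length(free) >= 1L, !is.null(names(free)))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[2L] < b[1L]) {
      stop(sprintf("bounds for '%s' must be finite c(lower, upper)", nm))
    }
    known <- c(names(unclass(params)), "init_total", "cases_growth",
               "uptake_growth")
    if (!nm %in% known) stop(sprintf("unknown free quantity '%s'", nm))
  }
  if (!is.data.frame(anchors) || nrow(anchors) < 1L) {
    stop("at least one anchor is required")
  }
  if (!"ref" %in% names(anchors)) anchors$ref <- NA_character_
  if (any(anchors$value <= 0)) stop("anchor values must be positive")
  if (any(anchors$year < grid$t0 - 1e-9 | anchors$year > grid$t1 + 1e-9)) {
    stop("anchor years must lie within the simulation horizon")
  }
  structure(list(free = free, anchors = anchors, grid = grid,
                 params = params, exo = exo, state0 = state0,
                 grid_points = as.integer(grid_points), seed = seed),
            class = "calibration_problem")
}

# Apply a named vector of free-quantity values to (params, exo).
apply_free_values <- function(values, params, exo) {
  p <- unclass(params)
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm == "init_total") {
      p$di <- v / 2
      p$ci <- v / 2
    } else if (nm == "cases_growth") {
      exo$cases$extrapolation_rate <- v
    } else if (nm == "uptake_growth") {
      exo$uptake$extrapolation_rate <- v
    } else {
      p[[nm]] <- v
    }
  }
  class(p) <- "sadcwc_params"
  list(params = p, exo = exo)
}

# Annual stock table for a candidate parameterisation.
simulate_annual <- function(params, exo, grid, state0, method = "euler") {
  traj <- integrate_stocks(
    function(state, t) sadcwc_flow_values(state, params, exo, t),
    state0, grid, method = method, flows = sadcwc_flow_table())
  annual_states(traj)
}

#' Calibration loss: sum of squared relative errors
#'
#' For level anchors the residual is `(sim - obs) / obs` for the stock at
#' the anchor year; for ratio anchors (`ref` set) the simulated quantity
#' is `stock / ref`. Relative errors are used because the stocks span
#' three orders of magnitude.
#'
#' @param values named numeric vector of free-quantity values.
#' @param problem a [calibration_problem()].
#' @return List with `loss` (non-negative scalar) and `residuals`
#'   (per-anchor relative errors).
#' @export
calibration_loss <- function(values, problem) {
  ap <- apply_free_values(values, problem$params, problem$exo)
  ann <- simulate_annual(ap$params, ap$exo, problem$grid, problem$state0)
  a <- problem$anchors
  res <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    row <- which(ann$year == a$year[i])
    if (!length(row)) {
      stop(sprintf("anchor year %s not on the reporting grid", a$year[i]))
    }
    sim <- ann[[a$stock[i]]][row]
    if (!is.na(a$ref[i])) sim <- sim / ann[[a$ref[i]]][row]
    res[i] <- (sim - a$value[i]) / a$value[i]
  }
  list(loss = sum(res^2), residuals = res)
}

#' Calibrate the free parameters within their bounds
#'
#' Deterministic coarse-to-fine search: the loss is evaluated on a full
#' factorial grid over the bounded box (`grid_points` per dimension,
#' degenerate dimensions collapse to their single value), then refined
#' from the best grid point with box-constrained quasi-Newton iteration
#' ([stats::nlminb()]). No randomness is involved, so results are exactly
#' reproducible.
#'
#' @param problem a [calibration_problem()].
#' @param refine run the local refinement stage (default `TRUE`).
#' @return An object of class `calibration_result`: list with
#'   `fitted_values` (named vector of free quantities), `params` (full
#'   fitted parameter set), `exo` (fitted exogenous flows), `loss`,
#'   `residuals` (per-anchor, relative), `anchors`, `convergence`
#'   (`TRUE` if the refinement converged or was skipped) and `n_eval`.
#' @examples
#' \donttest{
#' fit <- calibrate(calibration_problem())
#' fit$fitted_values
#' }
#' @export
calibrate <- function(problem, refine = TRUE) {
  stopifnot(inherits(problem, "calibration_problem"))
  free <- problem$free
  lower <- vapply(free, `[`, numeric(1), 1L)
  upper <- vapply(free, `[`, numeric(1), 2L)
  n_eval <- 0L
  obj <- function(x) {
    names(x) <- names(free)
    n_eval <<- n_eval + 1L
    calibration_loss(x, problem)$loss
  }
  axes <- lapply(seq_along(free), function(i) {
    if (upper[i] - lower[i] < 1e-12) lower[i] else
      seq(lower[i], upper[i], length.out = problem$grid_points)
  })
  cand <- as.matrix(expand.grid(axes))
  colnames(cand) <- names(free)
  losses <- apply(cand, 1L, obj)
  best <- which.min(losses)
  x0 <- cand[best, ]
  fit_loss <- losses[best]
  convergence <- TRUE
  if (refine && any(upper - lower > 1e-12)) {
    # abs.tol = 0 matters: near-perfect fits have losses close to zero and
    # the default absolute tolerance would stop the iteration prematurely.
    opt <- stats::nlminb(x0, obj, lower = lower, upper = upper,
                         control = list(rel.tol = 1e-13, abs.tol = 0,
                                        iter.max = 500L, eval.max = 1000L))
    opt2 <- stats::nlminb(opt$par, obj, lower = lower, upper = upper,
                          control = list(rel.tol = 1e-13, abs.tol = 0,
                                         iter.max = 500L, eval.max = 1000L))
    if (opt2$objective <= opt$objective) opt <- opt2
    if (opt$objective <= fit_loss) {
      x0 <- opt$par
      fit_loss <- opt$objective
    }
    convergence <- opt$convergence == 0 || opt$objective <= fit_loss
  }
  names(x0) <- names(free)
  ap <- apply_free_values(x0, problem$params, problem$exo)
  final <- calibration_loss(x0, problem)
  structure(list(fitted_values = x0, params = ap$params, exo = ap$exo,
                 loss = final$loss, residuals = final$residuals,
                 anchors = problem$anchors, convergence = convergence,
                 n_eval = n_eval),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  fitted: ",
      paste(sprintf("%s = %.5g", names(x$fitted_values), x$fitted_values),
            collapse = ", "),
      sprintf("\n  loss = %.6g over %d anchor(s), converged: %s\n",
              x$loss, length(x$residuals), x$convergence))
  invisible(x)
}

#' Read calibration anchors from CSV
#'
#' @param path CSV with columns `year`, `stock`, `value` and optionally
#'   `ref`.
#' @return Anchor `data.frame`.
#' @export
read_anchors_csv <- function(path) {
  a <- utils::read.csv(path)
  need <- c("year", "stock", "value")
  if (!all(need %in% names(a))) {
    stop("anchor file must have columns year, stock, value")
  }
  if (!nrow(a)) stop("anchor file is empty")
  if (!"ref" %in% names(a)) a$ref <- NA_character_
  a
}
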