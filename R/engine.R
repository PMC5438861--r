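# Generic fixed-step stock-and-flow machinery: time grids, intervention
# ramps, flow records, proportional outflow limiting and euler/rk4
# integration. Nothing in this file knows about the SADC-WC model.

#' Simulation time grid
#'
#' Defines a fixed-step grid over a calendar horizon. Time is measured in
#' decimal calendar years (2004.0, 2004.0833, ...), the convention used
#' throughout the package; the step `dt` is in years.
#'
#' @param t0 start of the horizon (decimal calendar year).
#' @param t1 end of the horizon (decimal calendar year), `t1 > t0`.
#' @param dt step length in years; the default 1/12 corresponds to monthly
#'   stepping, the granularity typical of fixed-step system-dynamics engines.
#'
#' @return An object of class `time_grid` with elements `t0`, `t1`, `dt` and
#'   `n_steps`.
#' @examples
#' g <- time_grid(2004, 2019)
#' g$n_steps
#' @export
time_grid <- function(t0, t1, dt = 1 / 12) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(t1), length(t1) == 1L, is.finite(t1),
            is.numeric(dt), length(dt) == 1L, is.finite(dt))
  if (t1 <= t0) stop("'t1' must be greater than 't0'")
  if (dt <= 0) stop("'dt' must be positive")
  n <- (t1 - t0) / dt
  if (abs(n - round(n)) > 1e-8) {
    stop("(t1 - t0) must be a whole number of steps of length 'dt'")
  }
  structure(list(t0 = t0, t1 = t1, dt = dt, n_steps = as.integer(round(n))),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %.4g to %.4g by dt = %.6g (%d steps)\n",
              x$t0, x$t1, x$dt, x$n_steps))
  invisible(x)
}

#' Grid evaluation times
#'
#' @param grid a [time_grid()].
#' @return Numeric vector of the `n_steps + 1` grid times.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (0:grid$n_steps) * grid$dt
}

#' Linear intervention ramp on a parameter
#'
#' A time-linear override of a single model parameter: the value is
#' `v_start` up to `year_start`, `v_end` from `year_end` on, and linearly
#' interpolated in between. Ramps clamp outside the window rather than
#' extrapolate, so an intervention holds its final level after the ramp
#' period ends.
#'
#' @param parameter name of the parameter being ramped.
#' @param v_start value at and before `year_start`.
#' @param v_end value at and after `year_end`.
#' @param year_start,year_end calendar years delimiting the ramp,
#'   `year_end > year_start`.
#' @return An object of class `intervention_ramp`.
#' @examples
#' r <- intervention_ramp("c", 0.25, 0.5, 2014, 2019)
#' ramp_value(r, c(2013, 2016.5, 2020))
#' @export
intervention_ramp <- function(parameter, v_start, v_end, year_start, year_end) {
  stopifnot(is.character(parameter), length(parameter) == 1L,
            is.numeric(v_start), is.numeric(v_end),
            is.numeric(year_start), is.numeric(year_end))
  if (year_end <= year_start) stop("'year_end' must be greater than 'year_start'")
  structure(list(parameter = parameter, v_start = v_start, v_end = v_end,
                 year_start = year_start, year_end = year_end),
            class = "intervention_ramp")
}

#' Evaluate an intervention ramp
#'
#' @param ramp an [intervention_ramp()].
#' @param t calendar time(s), decimal years; vectorised.
#' @return Ramp value(s) at `t`: piecewise linear, continuous, clamped to the
#'   endpoint values outside `[year_start, year_end]`.
#' @export
ramp_value <- function(ramp, t) {
  stopifnot(inherits(ramp, "intervention_ramp"), is.numeric(t))
  frac <- (t - ramp$year_start) / (ramp$year_end - ramp$year_start)
  frac <- pmin(pmax(frac, 0), 1)
  ramp$v_start + frac * (ramp$v_end - ramp$v_start)
}

#' Flow record table
#'
#' A flow record names a flow, its source stock, its sink stock and its
#' current value (per year). Source or sink may be `"EXTERNAL"` for flows
#' crossing the model boundary (births, deaths, exogenous case reports).
#'
#' @param name character vector of flow names.
#' @param source,sink character vectors of stock names or `"EXTERNAL"`.
#' @param value numeric flow values (per year); defaults to `NA` for a
#'   topology-only template.
#' @return A `data.frame` with columns `name`, `source`, `sink`, `value`.
#' @export
flow_records <- function(name, source, sink, value = NA_real_) {
  stopifnot(is.character(name), is.character(source), is.character(sink))
  data.frame(name = name, source = source, sink = sink,
             value = rep_len(as.numeric(value), length(name)))
}

#' Incidence matrix of a flow topology
#'
#' @param flow_table a flow-record table (the `value` column is ignored).
#' @param stock_names names of the stocks, in state order.
#' @return A `length(stock_names)` x `nrow(flow_table)` matrix with entries
#'   -1 (flow leaves the stock), +1 (flow enters) and 0; `EXTERNAL`
#'   endpoints contribute nothing.
#' @export
incidence_matrix <- function(flow_table, stock_names) {
  m <- matrix(0, nrow = length(stock_names), ncol = nrow(flow_table),
              dimnames = list(stock_names, flow_table$name))
  for (j in seq_len(nrow(flow_table))) {
    src <- flow_table$source[j]
    snk <- flow_table$sink[j]
    if (src %in% stock_names) m[src, j] <- m[src, j] - 1
    if (snk %in% stock_names) m[snk, j] <- m[snk, j] + 1
  }
  m
}

#' Proportional outflow limiting
#'
#' Prevents negative stocks under fixed-step integration: for each stock,
#' if the total outflow over one step of length `dt` exceeds the current
#' level, all outflows of that stock are scaled by the common factor
#' `level / (total outflow * dt)`. Inflows are never touched, so a limited
#' flow removes from its source exactly what it delivers to its sink.
#'
#' @param state named non-negative numeric vector of stock levels.
#' @param flows flow-record `data.frame` (see [flow_records()]) with
#'   non-negative values computed from `state`.
#' @param dt step length in years.
#' @return `flows` with the `value` column rescaled where limiting applied.
#' @examples
#' st <- c(A = 10)
#' fl <- flow_records(c("f1", "f2"), c("A", "A"), c("EXTERNAL", "EXTERNAL"),
#'                    c(6, 6))
#' limit_outflows(st, fl, dt = 1)$value  # 5, 5
#' @export
limit_outflows <- function(state, flows, dt) {
  stopifnot(is.numeric(state), !is.null(names(state)),
            is.data.frame(flows), dt > 0)
  for (stk in names(state)) {
    idx <- which(flows$source == stk)
    if (!length(idx)) next
    tot <- sum(flows$value[idx]) * dt
    lvl <- state[[stk]]
    if (tot > lvl && tot > 0) {
      flows$value[idx] <- flows$value[idx] * (lvl / tot)
    }
  }
  flows
}

# Fast internal limiter on a bare value vector; `out_idx` is a list mapping
# each stock to the integer positions of its outflows in `values`.
limit_values <- function(state, values, out_idx, dt) {
  for (i in seq_along(state)) {
    idx <- out_idx[[i]]
    if (!length(idx)) next
    tot <- sum(values[idx]) * dt
    lvl <- state[[i]]
    if (tot > lvl && tot > 0) values[idx] <- values[idx] * (lvl / tot)
  }
  values
}

check_finite_flows <- function(values, names, t) {
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("non-finite flow value for '%s' at t = %.6g",
                 names[bad[1L]], t), call. = FALSE)
  }
}

#' Fixed-step integration of a stock-and-flow system
#'
#' Integrates a system of stocks forward on a fixed grid with the explicit
#' Euler method (the default, matching conventional system-dynamics engines)
#' or classical fourth-order Runge-Kutta. The system is specified either as
#'
#' * a *flow function* together with a flow-record `flows` template:
#'   `fn(state, t)` returns the numeric flow values (per year) aligned with
#'   the rows of `flows`; stock derivatives are assembled through the flow
#'   topology and per-step proportional outflow limiting keeps every stock
#'   non-negative (see [limit_outflows()]); or
#' * a *derivative function* (`flows = NULL`): `fn(state, t)` returns named
#'   per-stock derivatives directly; no limiting is applied. This form is
#'   intended for simple test systems.
#'
#' With rk4 and limiting, the limiter is applied at every stage evaluation
#' using the full step length; the final state is additionally clamped at
#' zero to absorb round-off from stage mixing.
#'
#' @param fn flow or derivative function `function(state, t)`.
#' @param state0 named non-negative numeric vector of initial stock levels.
#' @param grid a [time_grid()].
#' @param method `"euler"` (default) or `"rk4"`.
#' @param flows optional flow-record template (`name`, `source`, `sink`);
#'   when supplied, `fn` must return one value per row.
#' @param limit apply proportional outflow limiting (only meaningful with a
#'   `flows` template). Default `TRUE` when `flows` is given.
#'
#' @return An object of class `sf_trajectory`: a list with `times` (grid
#'   times), `states` (matrix, one row per grid time), `flows` (matrix of
#'   post-limiting flow values evaluated at each grid time, or `NULL`),
#'   `flow_table`, `grid` and `method`.
#' @examples
#' # one stock growing at 2.3%/yr, single Euler step
#' tr <- integrate_stocks(function(s, t) c(C = 0.023 * s[["C"]]),
#'                        c(C = 1000), time_grid(2004, 2005, dt = 1))
#' tr$states["2005", "C"]  # 1023
#' @export
integrate_stocks <- function(fn, state0, grid, method = c("euler", "rk4"),
                             flows = NULL, limit = !is.null(flows)) {
  method <- match.arg(method)
  stopifnot(is.function(fn), is.numeric(state0), !is.null(names(state0)),
            inherits(grid, "time_grid"))
  if (any(state0 < 0)) stop("initial state must be non-negative")
  if (limit && is.null(flows)) stop("'limit' requires a 'flows' template")

  times <- grid_times(grid)
  dt <- grid$dt
  n <- grid$n_steps
  stocks <- names(state0)

  states <- matrix(NA_real_, nrow = n + 1L, ncol = length(stocks),
                   dimnames = list(format_year(times), stocks))
  states[1L, ] <- state0

  if (!is.null(flows)) {
    inc <- incidence_matrix(flows, stocks)
    out_idx <- lapply(stocks, function(s) which(flows$source == s))
    flow_hist <- matrix(NA_real_, nrow = n + 1L, ncol = nrow(flows),
                        dimnames = list(format_year(times), flows$name))
    # returns named derivative vector from (possibly limited) flow values
    eval_deriv <- function(state, t, record_row = NA_integer_) {
      v <- as.numeric(fn(state, t))
      check_finite_flows(v, flows$name, t)
      if (limit) v <- limit_values(state, v, out_idx, dt)
      if (!is.na(record_row)) flow_hist[record_row, ] <<- v
      drop(inc %*% v)
    }
  } else {
    flow_hist <- NULL
    eval_deriv <- function(state, t, record_row = NA_integer_) {
      v <- fn(state, t)
      check_finite_flows(as.numeric(v), names(v), t)
      v[stocks]
    }
  }

  state <- state0
  for (i in seq_len(n)) {
    t <- times[i]
    if (method == "euler") {
      k1 <- eval_deriv(state, t, record_row = i)
      state <- state + dt * k1
    } else {
      k1 <- eval_deriv(state, t, record_row = i)
      k2 <- eval_deriv(pmax(state + dt / 2 * k1, 0), t + dt / 2)
      k3 <- eval_deriv(pmax(state + dt / 2 * k2, 0), t + dt / 2)
      k4 <- eval_deriv(pmax(state + dt * k3, 0), t + dt)
      state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (limit) state <- pmax(state, 0)
    states[i + 1L, ] <- state
  }
  # record flows at the final grid point for reporting
  if (!is.null(flows)) eval_deriv(state, times[n + 1L], record_row = n + 1L)

  structure(list(times = times, states = states, flows = flow_hist,
                 flow_table = flows, grid = grid, method = method),
            class = "sf_trajectory")
}

format_year <- function(t) formatC(t, format = "fg", digits = 10)

#' @export
print.sf_trajectory <- function(x, ...) {
  cat(sprintf("<sf_trajectory> %d stocks, %d grid points (%s), %.4g-%.4g\n",
              ncol(x$states), length(x$times), x$method,
              x$grid$t0, x$grid$t1))
  print(utils::head(annual_states(x)))
  invisible(x)
}

#' Annual stock snapshots of a trajectory
#'
#' Regardless of the integration step, reporting is on whole calendar years.
#'
#' @param traj an `sf_trajectory`.
#' @return `data.frame` with columns `year` and one column per stock.
#' @export
annual_states <- function(traj) {
  stopifnot(inherits(traj, "sf_trajectory"))
  keep <- abs(traj$times - round(traj$times)) < 1e-6
  out <- data.frame(year = round(traj$times[keep]))
  cbind(out, as.data.frame(traj$states[keep, , drop = FALSE],
                           row.names = seq_len(sum(keep))))
}

#' Tidy (long) form of a trajectory
#'
#' @param x an `sf_trajectory`.
#' @param row.names,optional,... ignored; present for the generic.
#' @param annual keep only whole-year grid points (default `TRUE`).
#' @return `data.frame` with columns `year`, `type` (`"stock"` or `"flow"`),
#'   `name`, `value`. Flow values are per year, post limiting.
#' @export
as.data.frame.sf_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        annual = TRUE, ...) {
  keep <- if (annual) abs(x$times - round(x$times)) < 1e-6 else
    rep(TRUE, length(x$times))
  yrs <- x$times[keep]
  st <- x$states[keep, , drop = FALSE]
  out <- data.frame(
    year = rep(yrs, times = ncol(st)),
    type = "stock",
    name = rep(colnames(st), each = length(yrs)),
    value = as.vector(st)
  )
  if (!is.null(x$flows)) {
    fl <- x$flows[keep, , drop = FALSE]
    out <- rbind(out, data.frame(
      year = rep(yrs, times = ncol(fl)),
      type = "flow",
      name = rep(colnames(fl), each = length(yrs)),
      value = as.vector(fl)
    ))
  }
  out
}

#' Write a trajectory to tidy CSV
#'
#' Columns: `year`, `type` (stock or flow), `name`, `value`.
#'
#' @param traj an `sf_trajectory`.
#' @param path output file path.
#' @param annual annual snapshots only (default) or every grid point.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, annual = TRUE) {
  utils::write.csv(as.data.frame(traj, annual = annual), path,
                   row.names = FALSE)
  invisible(path)
}
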