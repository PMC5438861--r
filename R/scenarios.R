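# Scenario machinery: hindcast, baseline projection and the three
# intervention experiments (linear parameter ramps over 2014-2019),
# with summaries and comparison helpers.

#' Scenario specification
#'
#' @param name scenario label.
#' @param grid simulation horizon, a [time_grid()].
#' @param ramps list of [intervention_ramp()]s; each must name an existing
#'   numeric parameter and its window must lie within the horizon.
#' @param param_overrides named list of parameter replacements applied
#'   before any ramps.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, grid, ramps = list(),
                          param_overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(grid, "time_grid"), is.list(ramps))
  for (rp in ramps) {
    stopifnot(inherits(rp, "intervention_ramp"))
    if (rp$year_start < grid$t0 - 1e-9 || rp$year_end > grid$t1 + 1e-9) {
      stop(sprintf("ramp on '%s' (%g-%g) outside the horizon %g-%g",
                   rp$parameter, rp$year_start, rp$year_end,
                   grid$t0, grid$t1))
    }
  }
  structure(list(name = name, grid = grid, ramps = ramps,
                 param_overrides = param_overrides),
            class = "scenario_spec")
}

#' Hindcast scenario over the historical window
#'
#' @param t0,t1 horizon, default 2004-2014.
#' @param dt integration step, default 1/12 year.
#' @return A `scenario_spec` with no ramps.
#' @export
hindcast_scenario <- function(t0 = 2004, t1 = 2014, dt = 1 / 12) {
  scenario_spec("hindcast", time_grid(t0, t1, dt))
}

#' Baseline projection scenario
#'
#' Business-as-usual projection: no parameter ramps, exogenous series
#' extrapolated at their historical mean growth.
#'
#' @param t0,t1 horizon, default 2004-2019.
#' @param dt integration step, default 1/12 year.
#' @return A `scenario_spec` with no ramps.
#' @export
baseline_scenario <- function(t0 = 2004, t1 = 2019, dt = 1 / 12) {
  scenario_spec("baseline", time_grid(t0, t1, dt))
}

#' The three published intervention scenarios
#'
#' Each intervention ramps one or two parameters linearly over 2014-2019
#' and holds the final value thereafter:
#'
#' 1. *Increased convictions*: the court fraction `c` and the
#'    successful-conviction fraction `s` both double, 0.25 to 0.5.
#' 2. *Increased correctional referrals*: the referral rate `cc` rises
#'    from its baseline value to 0.10.
#' 3. *Reduced relapse*: the relapse rate `r` falls from 0.257 to 0.127.
#'
#' @param kind intervention number, 1, 2 or 3.
#' @param params baseline parameter set supplying the ramp start values.
#' @param year_start,year_end ramp window, default 2014-2019.
#' @param t0,t1,dt horizon of the scenario, default 2004-2019 at monthly
#'   steps.
#' @return A `scenario_spec`.
#' @examples
#' make_intervention(3)$ramps[[1]]$v_end  # 0.127
#' @export
make_intervention <- function(kind, params = sadcwc_params(),
                              year_start = 2014, year_end = 2019,
                              t0 = 2004, t1 = 2019, dt = 1 / 12) {
  if (!kind %in% 1:3) stop("'kind' must be 1, 2 or 3")
  grid <- time_grid(t0, t1, dt)
  ramps <- switch(as.character(kind),
    "1" = list(
      intervention_ramp("c", params$c, 0.5, year_start, year_end),
      intervention_ramp("s", params$s, 0.5, year_start, year_end)),
    "2" = list(
      intervention_ramp("cc", params$cc, 0.10, year_start, year_end)),
    "3" = list(
      intervention_ramp("r", params$r, 0.127, year_start, year_end)))
  scenario_spec(paste0("int", kind), grid, ramps)
}

#' Run a scenario
#'
#' Simulates the SADC-WC system under a scenario specification: parameter
#' overrides are applied, ramped parameters are re-evaluated at every
#' integration step, and the trajectory is integrated with per-step outflow
#' limiting.
#'
#' @param spec a [scenario_spec()].
#' @param params baseline [sadcwc_params()].
#' @param exo an [exogenous_flows()] container.
#' @param state0 initial state, default [sadcwc_initial_state()].
#' @param method integration method, `"euler"` (default) or `"rk4"`.
#' @return An object of class `sadcwc_result`: list with `spec`,
#'   `trajectory` (an `sf_trajectory`) and `summary`
#'   (see [scenario_summary()]).
#' @examples
#' \donttest{
#' res <- run_scenario(baseline_scenario(), sadcwc_params(),
#'                     exogenous_flows())
#' res$summary$stocks
#' }
#' @export
run_scenario <- function(spec, params = sadcwc_params(),
                         exo = exogenous_flows(),
                         state0 = sadcwc_initial_state(),
                         method = "euler") {
  stopifnot(inherits(spec, "scenario_spec"), inherits(params, "sadcwc_params"))
  if (length(spec$param_overrides)) {
    params <- do.call(update_params, c(list(params), spec$param_overrides,
                                       list(enforce_bounds = FALSE)))
  }
  for (rp in spec$ramps) {
    if (!rp$parameter %in% names(params) ||
        !is.numeric(params[[rp$parameter]])) {
      stop(sprintf("ramp references unknown parameter '%s'", rp$parameter))
    }
  }
  p_t <- unclass(params)
  flow_fn <- if (length(spec$ramps)) {
    function(state, t) {
      p <- p_t
      for (rp in spec$ramps) p[[rp$parameter]] <- ramp_value(rp, t)
      sadcwc_flow_values(state, p, exo, t)
    }
  } else {
    function(state, t) sadcwc_flow_values(state, p_t, exo, t)
  }
  traj <- integrate_stocks(flow_fn, state0, spec$grid, method = method,
                           flows = sadcwc_flow_table())
  structure(list(spec = spec, trajectory = traj,
                 summary = scenario_summary(traj, name = spec$name)),
            class = "sadcwc_result")
}

#' Summarise a simulated trajectory
#'
#' @param traj an `sf_trajectory` (or a `sadcwc_result`, whose trajectory
#'   is used).
#' @param name scenario label carried into the summary.
#' @return An object of class `scenario_summary`: list with
#'   `stocks` (per-stock start/end values and percent change),
#'   `annual_flows` (flow values at each whole year, per year),
#'   `conviction_ratio` (annual ratio of new cases to successful
#'   convictions, the model's measure of criminal-justice throughput).
#' @export
scenario_summary <- function(traj, name = "scenario") {
  if (inherits(traj, "sadcwc_result")) traj <- traj$trajectory
  stopifnot(inherits(traj, "sf_trajectory"))
  ann <- annual_states(traj)
  first <- ann[1L, ]
  last <- ann[nrow(ann), ]
  stocks <- data.frame(
    stock = SADCWC_STOCKS,
    start_year = first$year, end_year = last$year,
    start = unlist(first[SADCWC_STOCKS], use.names = FALSE),
    end = unlist(last[SADCWC_STOCKS], use.names = FALSE)
  )
  stocks$pct_change <- ifelse(stocks$start > 0,
                              100 * (stocks$end - stocks$start) / stocks$start,
                              NA_real_)
  keep <- abs(traj$times - round(traj$times)) < 1e-6
  fl <- as.data.frame(traj$flows[keep, , drop = FALSE])
  fl <- cbind(year = round(traj$times[keep]), fl)
  ratio <- data.frame(year = fl$year,
                      ratio = ifelse(fl$successful_convictions > 0,
                                     fl$cases / fl$successful_convictions,
                                     NA_real_))
  structure(list(name = name, stocks = stocks, annual_flows = fl,
                 conviction_ratio = ratio),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("<scenario_summary> %s\n", x$name))
  print(x$stocks, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
print.sadcwc_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Percent change between two values
#'
#' `100 * (end - start) / start`; e.g. the published national arrest
#' counts 19,940 to 82,062 give a 311.5% increase.
#'
#' @param start positive reference value.
#' @param end final value.
#' @return Percent change.
#' @examples
#' percent_change(19940, 82062)  # 311.5
#' @export
percent_change <- function(start, end) {
  if (any(start <= 0)) stop("'start' must be positive")
  100 * (end - start) / start
}

#' Stock value at a whole calendar year
#'
#' @param result a `sadcwc_result` or `sf_trajectory`.
#' @param stock stock name.
#' @param year whole calendar year on the reporting grid.
#' @return Numeric stock level.
#' @export
stock_at <- function(result, stock, year) {
  traj <- if (inherits(result, "sadcwc_result")) result$trajectory else result
  ann <- annual_states(traj)
  row <- which(ann$year == year)
  if (!length(row)) stop(sprintf("year %s not on the reporting grid", year))
  ann[[stock]][row]
}

#' Base-graphics plot of a scenario result
#'
#' @param x a `sadcwc_result`.
#' @param log plot stocks on a log scale (default `TRUE`).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sadcwc_result <- function(x, log = TRUE, ...) {
  ann <- annual_states(x$trajectory)
  m <- as.matrix(ann[SADCWC_STOCKS])
  graphics::matplot(ann$year, m, type = "l", lty = 1, lwd = 2,
                    log = if (log) "y" else "", xlab = "year",
                    ylab = "stock level", main = x$spec$name, ...)
  graphics::legend("topleft", legend = SADCWC_STOCKS, lty = 1, lwd = 2,
                   col = seq_along(SADCWC_STOCKS), bty = "n")
  invisible(x)
}

#' Compare scenario end states against a baseline
#'
#' @param baseline a `sadcwc_result` taken as reference.
#' @param ... further `sadcwc_result`s.
#' @return `data.frame` with one row per scenario and stock: end-of-horizon
#'   level, percent change over the horizon, and difference vs. the
#'   baseline end level.
#' @export
compare_scenarios <- function(baseline, ...) {
  results <- c(list(baseline), list(...))
  tabs <- lapply(results, function(r) {
    s <- r$summary$stocks
    data.frame(scenario = r$summary$name, stock = s$stock, end = s$end,
               pct_change = s$pct_change)
  })
  out <- do.call(rbind, tabs)
  base <- tabs[[1L]]
  out$diff_vs_baseline <- out$end - base$end[match(out$stock, base$stock)]
  out
}
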