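# Reconstruction of the two data-driven converters (rehabilitation uptake
# and drug-related crime cases) as anchored growth series, plus the
# synthetic-observation generator used for calibration and
# parameter-recovery testing.

#' Anchored exogenous series
#'
#' A time-indexed annual driver defined by anchor points, an interpolation
#' model and an extrapolation rate. Geometric (constant relative growth)
#' interpolation is log-linear between consecutive anchors; linear
#' interpolation is available as an alternative. Beyond the last anchor the
#' series grows at `extrapolation_rate` per year; by default that rate is
#' the mean annual growth implied by the first and last anchors, so a
#' single-anchor series requires an explicit rate.
#'
#' @param anchors `data.frame` with columns `year` and `value`
#'   (non-negative); at least one row.
#' @param growth_model `"geometric"` (default) or `"linear"` interpolation
#'   between anchors.
#' @param extrapolation_rate per-year relative growth applied beyond the
#'   last anchor; must exceed -1. `NULL` (default) uses the implied mean
#'   annual growth between the first and last anchors.
#' @return An object of class `exo_series`.
#' @examples
#' s <- exo_series(data.frame(year = c(2004, 2013), value = c(4563, 7195)))
#' exo_value(s, c(2004, 2013, 2019))
#' s$extrapolation_rate  # ~0.0519
#' @export
exo_series <- function(anchors, growth_model = c("geometric", "linear"),
                       extrapolation_rate = NULL) {
  growth_model <- match.arg(growth_model)
  stopifnot(is.data.frame(anchors), all(c("year", "value") %in% names(anchors)),
            nrow(anchors) >= 1L)
  anchors <- anchors[order(anchors$year), c("year", "value")]
  if (anyDuplicated(anchors$year)) stop("anchor years must be distinct")
  if (any(!is.finite(anchors$value)) || any(anchors$value < 0)) {
    stop("anchor values must be finite and non-negative")
  }
  if (is.null(extrapolation_rate)) {
    if (nrow(anchors) < 2L) {
      stop("a single-anchor series needs an explicit 'extrapolation_rate'")
    }
    first <- anchors[1L, ]
    last <- anchors[nrow(anchors), ]
    if (first$value <= 0) {
      stop("implied growth undefined: first anchor value is zero")
    }
    extrapolation_rate <-
      (last$value / first$value)^(1 / (last$year - first$year)) - 1
  }
  if (extrapolation_rate <= -1) stop("'extrapolation_rate' must exceed -1")
  if (growth_model == "geometric" && nrow(anchors) >= 2L &&
      any(anchors$value == 0)) {
    stop("geometric interpolation requires positive anchor values; ",
         "use growth_model = \"linear\"")
  }
  structure(list(anchors = anchors, growth_model = growth_model,
                 extrapolation_rate = extrapolation_rate),
            class = "exo_series")
}

#' @export
print.exo_series <- function(x, ...) {
  cat(sprintf("<exo_series> %s, %d anchor(s), extrapolation %+.3f%%/yr\n",
              x$growth_model, nrow(x$anchors), 100 * x$extrapolation_rate))
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Evaluate an exogenous series
#'
#' @param series an [exo_series()].
#' @param t decimal year(s); vectorised. Times before the first anchor are
#'   an error; times beyond the last anchor extrapolate at the series'
#'   growth rate.
#' @return Numeric value(s) of the series at `t`.
#' @export
exo_value <- function(series, t) {
  stopifnot(inherits(series, "exo_series"), is.numeric(t))
  a <- series$anchors
  if (any(t < a$year[1L] - 1e-9)) {
    stop(sprintf("series undefined before its first anchor (%g)", a$year[1L]))
  }
  n <- nrow(a)
  out <- numeric(length(t))
  beyond <- t >= a$year[n] - 1e-12
  if (any(beyond)) {
    out[beyond] <- a$value[n] *
      (1 + series$extrapolation_rate)^(t[beyond] - a$year[n])
  }
  if (any(!beyond)) {
    out[!beyond] <- if (series$growth_model == "geometric") {
      exp(stats::approx(a$year, log(a$value), xout = t[!beyond])$y)
    } else {
      stats::approx(a$year, a$value, xout = t[!beyond])$y
    }
  }
  out
}

#' Rehabilitation-uptake series
#'
#' The annual flow of persons entering rehabilitation (D -> R) is a
#' data-driven converter in the model; the underlying admission counts are
#' anchored at 4,563 admissions in 2004 and 7,195 in 2013, interpolated
#' geometrically and extrapolated at the implied mean annual growth
#' (about 5.2% per year).
#'
#' @param first,last `c(year, value)` anchor pairs; defaults are the
#'   published admission counts.
#' @param horizon_end last year the series must cover; must not precede the
#'   last anchor.
#' @param growth_model passed to [exo_series()].
#' @return An `exo_series`.
#' @export
build_uptake_series <- function(first = c(2004, 4563), last = c(2013, 7195),
                                horizon_end = 2019,
                                growth_model = "geometric") {
  stopifnot(length(first) == 2L, length(last) == 2L)
  if (horizon_end < last[1L]) {
    stop("'horizon_end' must not precede the last anchor year")
  }
  exo_series(data.frame(year = c(first[1L], last[1L]),
                        value = c(first[2L], last[2L])),
             growth_model = growth_model)
}

#' Implied mean annual growth of the national drug-related arrest counts
#'
#' Annual drug-related arrests grew from 19,940 (2003/04) to 82,062
#' (2012/13), a 311.5% increase over nine years; the implied constant
#' annual growth rate is about 17.0% per year. Used as the default growth
#' assumption for the provincial crime-case series, whose own annual values
#' are not published.
#'
#' @param first,last arrest counts at the ends of the window.
#' @param years length of the window in years.
#' @return Per-year growth rate.
#' @export
default_cases_growth <- function(first = 19940, last = 82062, years = 9) {
  (last / first)^(1 / years) - 1
}

#' Drug-related crime-case series
#'
#' The annual flow of new drug-related crime cases (-> L) is a data-driven
#' converter; it is reconstructed as a geometric series from the published
#' 2004 base of 30,432 cases at a constant annual growth rate, by default
#' the rate implied by the national arrest counts
#' (see [default_cases_growth()]).
#'
#' @param base `c(year, value)`; default `c(2004, 30432)`.
#' @param annual_growth per-year growth rate, `> -1`.
#' @param horizon_end unused except for interface symmetry with
#'   [build_uptake_series()]; the series extrapolates indefinitely.
#' @return An `exo_series`.
#' @export
build_cases_series <- function(base = c(2004, 30432),
                               annual_growth = default_cases_growth(),
                               horizon_end = 2019) {
  stopifnot(length(base) == 2L)
  if (annual_growth <= -1) stop("'annual_growth' must exceed -1")
  exo_series(data.frame(year = base[1L], value = base[2L]),
             extrapolation_rate = annual_growth)
}

#' Exogenous-flow container
#'
#' @param uptake an `exo_series` for the rehabilitation-uptake flow
#'   (persons/year, D -> R).
#' @param cases an `exo_series` for the drug-related crime-case flow
#'   (cases/year, into L).
#' @return An object of class `exogenous_flows`.
#' @export
exogenous_flows <- function(uptake = build_uptake_series(),
                            cases = build_cases_series()) {
  stopifnot(inherits(uptake, "exo_series"), inherits(cases, "exo_series"))
  structure(list(uptake = uptake, cases = cases), class = "exogenous_flows")
}

#' All-zero exogenous flows
#'
#' Convenience container with both drivers identically zero, used in
#' conservation and decay tests.
#'
#' @param from first defined year (default 2000).
#' @return An `exogenous_flows` object.
#' @export
zero_exogenous <- function(from = 2000) {
  z <- exo_series(data.frame(year = from, value = 0), extrapolation_rate = 0)
  exogenous_flows(uptake = z, cases = z)
}

#' Read an exogenous series from CSV
#'
#' @param path CSV with columns `year`, `value` (anchor points).
#' @param ... passed to [exo_series()].
#' @return An `exo_series`.
#' @export
read_exo_csv <- function(path, ...) {
  exo_series(utils::read.csv(path), ...)
}

#' Write the anchors of an exogenous series to CSV
#'
#' @param series an `exo_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exo_csv <- function(series, path) {
  utils::write.csv(series$anchors, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic noisy observations of the simulated stocks
#'
#' Runs the model on `grid`, takes annual snapshots of all five stocks and
#' perturbs them with multiplicative log-normal noise:
#' `obs = true * exp(rnorm(0, sigma))`. Deterministic for a fixed seed;
#' `sigma = 0` returns the noiseless trajectory. Used as the fixture
#' generator for parameter-recovery tests.
#'
#' @param params a [sadcwc_params()] object.
#' @param exo an [exogenous_flows()] container.
#' @param grid a [time_grid()].
#' @param sigma log-scale noise standard deviation, `>= 0`.
#' @param seed integer RNG seed.
#' @param state0 initial state (default [sadcwc_initial_state()]).
#' @param method integration method (default `"euler"`).
#' @return `data.frame` with columns `year`, `stock`, `value`, and
#'   attributes `sigma` and `seed`.
#' @export
simulate_observations <- function(params, exo, grid, sigma = 0.05,
                                  seed = 1L,
                                  state0 = sadcwc_initial_state(),
                                  method = "euler") {
  if (sigma < 0) stop("'sigma' must be non-negative")
  traj <- integrate_stocks(
    function(state, t) sadcwc_flow_values(state, params, exo, t),
    state0, grid, method = method, flows = sadcwc_flow_table())
  ann <- annual_states(traj)
  long <- data.frame(
    year = rep(ann$year, times = length(SADCWC_STOCKS)),
    stock = rep(SADCWC_STOCKS, each = nrow(ann)),
    value = unlist(ann[SADCWC_STOCKS], use.names = FALSE)
  )
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    long$value <- long$value * exp(stats::rnorm(nrow(long), 0, sigma))
  }
  attr(long, "sigma") <- sigma
  attr(long, "seed") <- seed
  long
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
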