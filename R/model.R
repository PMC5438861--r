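# The SADC-WC model proper: stocks, the sixteen flow records, the
# derivative system, the sentence-completion rate and the initial-condition
# constructors.
#
# Stocks: C community at risk, D substance abusers / drug-related-crime
# participants, S correctional services, R rehabilitation (all persons),
# and L open drug-related crime cases (a case ledger, not persons).

SADCWC_STOCKS <- c("C", "D", "S", "R", "L")

#' Stock state of the SADC-WC system
#'
#' @param C community at risk (persons).
#' @param D substance abusers and drug-related-crime participants (persons).
#' @param S persons in correctional services.
#' @param R persons in rehabilitation.
#' @param L open drug-related crime cases (cases).
#' @return Named numeric vector `c(C, D, S, R, L)`.
#' @examples
#' stock_state(C = 4645600, D = 696840, S = 1902, R = 4563, L = 30432)
#' @export
stock_state <- function(C, D, S, R, L) {
  st <- c(C = C, D = D, S = S, R = R, L = L)
  if (any(!is.finite(st))) stop("stock levels must be finite")
  if (any(st < 0)) stop("stock levels must be non-negative")
  st
}

#' Flow topology of the SADC-WC system
#'
#' The sixteen flow records of the model. Convictions appear twice, as the
#' published converter table has it: `convictions` moves the convicted
#' person D -> S while `successful_convictions` closes the corresponding
#' case out of L; both carry the same value `s * c * L` (one case = one
#' person).
#'
#' @return A flow-record `data.frame` (see [flow_records()]) with `value`
#'   unset.
#' @export
sadcwc_flow_table <- function() {
  flow_records(
    name = c("inflow", "outflow", "initiation", "self_conviction",
             "uptake", "relapse", "cases", "convictions",
             "successful_convictions", "failed_convictions",
             "correctional_rehabilitation", "sentences_completed",
             "successful_rehabilitation", "deaths_D", "deaths_R",
             "deaths_S"),
    source = c("EXTERNAL", "C", "C", "D",
               "D", "R", "EXTERNAL", "D",
               "L", "L",
               "S", "S",
               "R", "D", "R", "S"),
    sink = c("C", "EXTERNAL", "D", "C",
             "R", "D", "L", "S",
             "EXTERNAL", "EXTERNAL",
             "R", "C",
             "C", "EXTERNAL", "EXTERNAL", "EXTERNAL")
  )
}

#' Successful-corrections (sentence-completion) rate
#'
#' The per-year rate at which sentenced offenders complete their time in
#' correctional services, derived from the sentence-duration mix as the
#' proportion-weighted sum of reciprocal median durations:
#' `sum(proportion_k / median_k)`. With the published mix (31% serving a
#' median of 2.5 years, 42% of 10, 10% of 12.5 and 16% of 30) this gives
#' 0.179 per year.
#'
#' @param mix a [sentence_mix()].
#' @return Rate per year (unrounded; round only for reporting).
#' @examples
#' round(successful_corrections_rate(sentence_mix(
#'   proportions = c(0.31, 0.42, 0.10, 0.16),
#'   medians = c(2.5, 10, 12.5, 30))), 3)  # 0.179
#' @export
successful_corrections_rate <- function(mix) {
  stopifnot(inherits(mix, "sentence_mix"))
  sum(mix$proportion / mix$median_duration)
}

#' Sentence-duration mix
#'
#' @param proportions fractions of offenders per sentence category; must
#'   sum to 1 within a tolerance of 0.015, which accommodates mixes quoted
#'   as rounded percentages (the published mix sums to 0.99 as printed and
#'   is used as printed). Pass `normalise = TRUE` to rescale exactly.
#' @param medians median sentence durations in years, all positive.
#' @param normalise rescale `proportions` to sum to 1 before validation.
#' @return An object of class `sentence_mix`.
#' @export
sentence_mix <- function(proportions, medians, normalise = FALSE) {
  stopifnot(is.numeric(proportions), is.numeric(medians),
            length(proportions) == length(medians), length(medians) >= 1L)
  if (any(medians <= 0)) stop("median durations must be positive")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (normalise) proportions <- proportions / sum(proportions)
  if (abs(sum(proportions) - 1) > 0.015) {
    stop("proportions must sum to 1 (use normalise = TRUE to rescale)")
  }
  structure(list(proportion = proportions, median_duration = medians),
            class = "sentence_mix")
}

#' Compute all flows of the SADC-WC system at a time point
#'
#' Evaluates the sixteen flow values (per year) from the current state, the
#' parameter set and the two exogenous series. Flow forms:
#' `inflow = b*C + m`, `outflow = d*C`,
#' `initiation = (di + ci)*C*D/N` (or bilinear, see [sadcwc_params()]),
#' `self_conviction = se*D`, `uptake` and `cases` from the exogenous
#' series, `relapse = r*R`,
#' `convictions = successful_convictions = s*c*L`,
#' `failed_convictions = fc*L`,
#' `correctional_rehabilitation = cc*R` (or `cc*S`),
#' `sentences_completed = sc*S`, `successful_rehabilitation = sr*R`,
#' and the three excess death flows `dd*D`, `rd*R`, `sd*S`.
#'
#' @param state named stock vector, see [stock_state()].
#' @param params a [sadcwc_params()] object.
#' @param exo an [exogenous_flows()] container.
#' @param t calendar time (decimal year).
#' @return Flow-record `data.frame` with the `value` column filled.
#' @export
compute_flows <- function(state, params, exo, t) {
  tbl <- sadcwc_flow_table()
  tbl$value <- sadcwc_flow_values(state, params, exo, t)
  tbl
}

# Bare numeric flow values aligned with sadcwc_flow_table(); the hot path
# used by the integrator.
sadcwc_flow_values <- function(state, params, exo, t) {
  C <- state[["C"]]; D <- state[["D"]]; S <- state[["S"]]
  R <- state[["R"]]; L <- state[["L"]]
  N <- C + D + S + R
  initiation <- if (params$initiation_form == "frequency") {
    if (N > 0) (params$di + params$ci) * C * D / N else 0
  } else {
    (params$di + params$ci) * C * D
  }
  referral <- params$cc * if (params$referral_base == "R") R else S
  sconv <- params$s * params$c * L
  c(inflow = params$b * C + params$m,
    outflow = params$d * C,
    initiation = initiation,
    self_conviction = params$se * D,
    uptake = exo_value(exo$uptake, t),
    relapse = params$r * R,
    cases = exo_value(exo$cases, t),
    convictions = sconv,
    successful_convictions = sconv,
    failed_convictions = params$fc * L,
    correctional_rehabilitation = referral,
    sentences_completed = params$sc * S,
    successful_rehabilitation = params$sr * R,
    deaths_D = params$dd * D,
    deaths_R = params$rd * R,
    deaths_S = params$sd * S)
}

#' Stock derivatives of the SADC-WC system
#'
#' Assembles the per-stock derivatives from the flow values through the
#' flow topology:
#' \deqn{dC/dt = inflow + successful\ rehabilitation + sentences\ completed
#'   + self\ conviction - outflow - initiation}
#' \deqn{dD/dt = initiation + relapse - uptake - convictions -
#'   self\ conviction - deaths_D}
#' \deqn{dS/dt = convictions - correctional\ rehabilitation -
#'   sentences\ completed - deaths_S}
#' \deqn{dR/dt = uptake + correctional\ rehabilitation -
#'   successful\ rehabilitation - relapse - deaths_R}
#' \deqn{dL/dt = cases - failed\ convictions - successful\ convictions}
#'
#' @inheritParams compute_flows
#' @return Named numeric vector of derivatives for `C, D, S, R, L`
#'   (per year).
#' @export
derivatives <- function(state, params, exo, t) {
  tbl <- sadcwc_flow_table()
  inc <- incidence_matrix(tbl, SADCWC_STOCKS)
  drop(inc %*% sadcwc_flow_values(state, params, exo, t))
}

#' Initial state from published sources
#'
#' Builds the initial stock vector the way the published initial-condition
#' table derives it: the abuser stock as a fraction of the total
#' population, the correctional stock from the initial case load times the
#' court and conviction fractions, and the community stock set to the full
#' population total (the published convention; set `disjoint = TRUE` to
#' exclude the abusers from C instead).
#'
#' @param pop_total total provincial population (persons).
#' @param abuser_fraction fraction of the population abusing substances.
#' @param cases0 initial open drug-related crime cases.
#' @param rehab0 initial persons in rehabilitation.
#' @param court_fraction fraction of cases reaching court.
#' @param conviction_fraction fraction of court cases convicting.
#' @param disjoint subtract the abuser stock from the community stock
#'   (default `FALSE`, the published convention).
#' @return A [stock_state()] vector.
#' @examples
#' initial_state_from_sources(4645600, 0.15, 30432, 4563, 0.25, 0.25)
#' @export
initial_state_from_sources <- function(pop_total, abuser_fraction, cases0,
                                       rehab0, court_fraction,
                                       conviction_fraction,
                                       disjoint = FALSE) {
  stopifnot(pop_total >= 0, cases0 >= 0, rehab0 >= 0)
  for (f in c(abuser_fraction, court_fraction, conviction_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  D <- abuser_fraction * pop_total
  stock_state(C = if (disjoint) pop_total - D else pop_total,
              D = D,
              S = cases0 * court_fraction * conviction_fraction,
              R = rehab0,
              L = cases0)
}

#' Default 2004 initial state of the SADC-WC system
#'
#' Western Cape, 2004: population 4,645,600; abusers 15% of the population
#' (696,840); 30,432 open drug-related crime cases; 4,563 persons in
#' rehabilitation; correctional stock 30,432 x 0.25 x 0.25 = 1,902.
#'
#' @param disjoint see [initial_state_from_sources()].
#' @return A [stock_state()] vector.
#' @export
sadcwc_initial_state <- function(disjoint = FALSE) {
  initial_state_from_sources(pop_total = 4645600, abuser_fraction = 0.15,
                             cases0 = 30432, rehab0 = 4563,
                             court_fraction = 0.25,
                             conviction_fraction = 0.25,
                             disjoint = disjoint)
}
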