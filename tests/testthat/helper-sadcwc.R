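# Shared fixtures: all tiny, built in code.

# constant-valued exogenous series defined from `from` onwards
const_series <- function(value, from = 2000) {
  exo_series(data.frame(year = from, value = value), extrapolation_rate = 0)
}

# parameter set with no demography and no excess deaths: C+D+S+R is closed
closed_params <- function(...) {
  sadcwc_params(b = 0, d = 0, m = 0, dd = 0, rd = 0, sd = 0,
                enforce_bounds = FALSE, ...)
}

# random non-negative parameter draw for stress tests (intentionally wider
# than the declared ranges)
random_params <- function() {
  sadcwc_params(
    b = runif(1, 0, 0.5), d = runif(1, 0, 0.5), r = runif(1, 0, 2),
    cc = runif(1, 0, 2), s = runif(1), c = runif(1), fc = runif(1),
    sr = runif(1), m = runif(1, 0, 5e5), sc = runif(1, 0, 2),
    di = runif(1, 0, 1), ci = runif(1, 0, 1), se = runif(1, 0, 1),
    dd = runif(1, 0, 0.5), rd = runif(1, 0, 0.5), sd = runif(1, 0, 0.5),
    enforce_bounds = FALSE)
}

random_state <- function() {
  stock_state(C = runif(1, 0, 1e6), D = runif(1, 0, 1e5),
              S = runif(1, 0, 1e4), R = runif(1, 0, 1e4),
              L = runif(1, 0, 1e5))
}

random_exo <- function() {
  exogenous_flows(
    uptake = exo_series(data.frame(year = 2000, value = runif(1, 0, 5e3)),
                        extrapolation_rate = runif(1, -0.1, 0.3)),
    cases = exo_series(data.frame(year = 2000, value = runif(1, 0, 5e4)),
                       extrapolation_rate = runif(1, -0.1, 0.3)))
}
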