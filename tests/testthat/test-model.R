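test_that("the sentence-completion rate reproduces the published mix and hand arithmetic", {
  printed <- sentence_mix(c(0.31, 0.42, 0.10, 0.16), c(2.5, 10, 12.5, 30))
  expect_equal(round(successful_corrections_rate(printed), 3), 0.179)
  expect_equal(successful_corrections_rate(sentence_mix(1, 1)), 1)
  expect_equal(successful_corrections_rate(sentence_mix(c(0.5, 0.5), c(2, 4))),
               0.375)
})

test_that("the sentence-completion rate is order-invariant and scales inversely with durations", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- runif(k); p <- p / sum(p)
    d <- runif(k, 0.5, 40)
    rate <- successful_corrections_rate(sentence_mix(p, d))
    perm <- sample(k)
    expect_equal(successful_corrections_rate(sentence_mix(p[perm], d[perm])),
                 rate)
    a <- runif(1, 0.5, 5)
    expect_equal(successful_corrections_rate(sentence_mix(p, a * d)),
                 rate / a)
  }
  expect_error(sentence_mix(c(0.5, 0.5), c(0, 4)), "positive")
  expect_error(sentence_mix(c(0.6, 0.6), c(1, 1)), "sum to 1")
  norm <- sentence_mix(c(2, 2), c(1, 1), normalise = TRUE)
  expect_equal(sum(norm$proportion), 1)
})

test_that("flow values at the 2004 initial state match hand arithmetic on the published inputs", {
  fl <- compute_flows(sadcwc_initial_state(), sadcwc_params(),
                      exogenous_flows(), 2004)
  v <- setNames(fl$value, fl$name)
  expect_equal(unname(v["inflow"]), 0.023 * 4645600 + 152230)  # 259078.8
  expect_equal(unname(v["successful_convictions"]), 0.25 * 0.25 * 30432)  # 1902
  expect_equal(unname(v["convictions"]), unname(v["successful_convictions"]))
  expect_equal(unname(v["uptake"]), 4563)
  expect_equal(unname(v["cases"]), 30432)
  expect_equal(unname(v["failed_convictions"]), 0.75 * 30432)
  expect_equal(unname(v["sentences_completed"]), 0.179 * 1902)
})

test_that("every flow is non-negative for non-negative states and parameters", {
  set.seed(11)
  for (i in 1:50) {
    fl <- compute_flows(random_state(), random_params(), random_exo(), 2005)
    expect_true(all(fl$value >= 0))
  }
})

test_that("an empty system with no migration has no endogenous flows", {
  st <- stock_state(0, 0, 0, 0, 0)
  exo <- exogenous_flows(uptake = const_series(3), cases = const_series(7))
  fl <- compute_flows(st, sadcwc_params(m = 0), exo, 2005)
  v <- setNames(fl$value, fl$name)
  expect_equal(unname(v["uptake"]), 3)
  expect_equal(unname(v["cases"]), 7)
  expect_true(all(v[setdiff(names(v), c("uptake", "cases"))] == 0))
})

test_that("derivatives conserve persons in a closed system and keep empty compartments empty", {
  exo0 <- zero_exogenous()
  set.seed(5)
  for (i in 1:20) {
    d <- derivatives(random_state(), closed_params(), exo0, 2005)
    expect_equal(unname(sum(d[c("C", "D", "S", "R")])), 0, tolerance = 1e-12)
  }
  # D = R = L = 0 with zero uptake: the abuser stock cannot move
  d <- derivatives(stock_state(C = 1e6, D = 0, S = 50, R = 0, L = 0),
                   sadcwc_params(), exo0, 2005)
  expect_equal(unname(d["D"]), 0)
})

test_that("the case ledger drains monotonically to zero without new cases", {
  params <- sadcwc_params()
  exo <- exogenous_flows(uptake = const_series(0), cases = const_series(0))
  tr <- integrate_stocks(
    function(s, t) sadcwc:::sadcwc_flow_values(s, params, exo, t),
    sadcwc_initial_state(), time_grid(2004, 2024, 1 / 12),
    flows = sadcwc_flow_table())
  L <- tr$states[, "L"]
  expect_true(all(diff(L) <= 0))
  expect_lt(L[length(L)], 1)
})

test_that("the derivative of the case ledger matches hand arithmetic at 2004", {
  d <- derivatives(sadcwc_initial_state(), sadcwc_params(),
                   exogenous_flows(), 2004)
  # dL = cases(2004) - (fc + s*c) * L0
  expect_equal(unname(d["L"]), 30432 - (0.75 + 0.0625) * 30432)
})

test_that("initial-state construction reproduces the published 2004 values", {
  st <- initial_state_from_sources(4645600, 0.15, 30432, 4563, 0.25, 0.25)
  expect_equal(unname(st["D"]), 696840)
  expect_equal(unname(st["S"]), 1902)
  expect_equal(unname(st["C"]), 4645600)
  expect_equal(unname(st["R"]), 4563)
  expect_equal(unname(st["L"]), 30432)
  expect_equal(sadcwc_initial_state(), st)
  # no abusers, no cases
  empty <- initial_state_from_sources(1000, 0, 0, 0, 0.25, 0.25)
  expect_equal(unname(empty), c(1000, 0, 0, 0, 0))
  # disjoint convention removes the abusers from the community stock
  dis <- sadcwc_initial_state(disjoint = TRUE)
  expect_equal(unname(dis["C"]), 4645600 - 696840)
})

test_that("parameter validation enforces declared ranges and fraction limits", {
  expect_error(sadcwc_params(di = 0.2), "declared range")
  expect_silent(sadcwc_params(di = 0.2, enforce_bounds = FALSE))
  expect_error(sadcwc_params(s = 1.5), "fraction")
  expect_error(sadcwc_params(b = -0.1), "non-negative")
  p <- update_params(sadcwc_params(), r = 0.127)
  expect_equal(p$r, 0.127)
  expect_error(update_params(sadcwc_params(), nope = 1), "unknown")
})

test_that("parameter files round-trip through YAML", {
  p <- sadcwc_params(di = 0.09, se = 0.05, referral_base = "S")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  expect_equal(read_params(path), p)
})

test_that("the bilinear initiation switch reproduces the raw printed product", {
  st <- sadcwc_initial_state()
  p <- sadcwc_params(initiation_form = "bilinear")
  fl <- compute_flows(st, p, exogenous_flows(), 2004)
  expect_equal(fl$value[fl$name == "initiation"],
               (p$di + p$ci) * st[["C"]] * st[["D"]])
  pf <- sadcwc_params()
  flf <- compute_flows(st, pf, exogenous_flows(), 2004)
  N <- sum(st[c("C", "D", "S", "R")])
  expect_equal(flf$value[flf$name == "initiation"],
               (pf$di + pf$ci) * st[["C"]] * st[["D"]] / N)
})
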