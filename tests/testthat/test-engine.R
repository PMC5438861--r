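test_that("time grids validate their construction and enumerate times", {
  g <- time_grid(2004, 2019, 1 / 12)
  expect_equal(g$n_steps, 180L)
  expect_length(grid_times(g), 181L)
  expect_equal(grid_times(g)[1], 2004)
  expect_equal(grid_times(g)[181], 2019)
  expect_error(time_grid(2010, 2004), "greater")
  expect_error(time_grid(2004, 2010, -1), "positive")
  expect_error(time_grid(2004, 2005, 0.3), "whole number")
})

test_that("intervention ramps are linear, clamped and attain both endpoints", {
  rc <- intervention_ramp("c", 0.25, 0.5, 2014, 2019)
  expect_equal(ramp_value(rc, 2014), 0.25)
  expect_equal(ramp_value(rc, 2016.5), 0.375)
  expect_equal(ramp_value(rc, 2019), 0.5)
  # clamping outside the window, not extrapolation
  expect_equal(ramp_value(rc, c(2000, 2025)), c(0.25, 0.5))
  # the published relapse-reduction ramp
  rr <- intervention_ramp("r", 0.257, 0.127, 2014, 2019)
  expect_equal(ramp_value(rr, 2019), 0.127)

  # property: monotone between endpoints, continuous, both endpoints exact
  set.seed(42)
  for (i in 1:25) {
    v <- sort(runif(2)); ys <- runif(1, 2000, 2010); ye <- ys + runif(1, 1, 10)
    up <- intervention_ramp("x", v[1], v[2], ys, ye)
    tt <- seq(ys - 1, ye + 1, length.out = 101)
    vals <- ramp_value(up, tt)
    expect_true(all(diff(vals) >= -1e-12))
    expect_equal(ramp_value(up, ys), v[1])
    expect_equal(ramp_value(up, ye), v[2])
  }
  expect_error(intervention_ramp("x", 1, 2, 2019, 2014), "greater")
})

test_that("a single Euler step reproduces closed-form growth and zero flows freeze the state", {
  tr <- integrate_stocks(function(s, t) c(C = 0.023 * s[["C"]]),
                         c(C = 1000), time_grid(2004, 2005, dt = 1))
  expect_equal(unname(tr$states[2, "C"]), 1023)

  # all flows identically zero: the trajectory is constant
  fl <- flow_records("f", "A", "B", NA)
  tr0 <- integrate_stocks(function(s, t) 0, c(A = 5, B = 7),
                          time_grid(2000, 2010, 1), flows = fl)
  expect_true(all(tr0$states[, "A"] == 5))
  expect_true(all(tr0$states[, "B"] == 7))
})

test_that("rk4 matches the exponential closed form and both methods converge at their orders", {
  b <- 0.023
  fn <- function(s, t) c(C = b * s[["C"]])
  closed <- 1000 * exp(b * 10)
  rk <- integrate_stocks(fn, c(C = 1000), time_grid(2004, 2014, 1),
                         method = "rk4")
  expect_lt(abs(rk$states[11, "C"] - closed) / closed, 1e-4)

  err <- function(method, dt) {
    tr <- integrate_stocks(fn, c(C = 1000), time_grid(2004, 2014, dt),
                           method = method)
    abs(tr$states[nrow(tr$states), "C"] - closed)
  }
  # halving dt halves the euler error (first order) ...
  expect_equal(err("euler", 0.5) / err("euler", 0.25), 2, tolerance = 0.1)
  # ... and cuts the rk4 error by ~2^4 (fourth order)
  expect_equal(err("rk4", 0.5) / err("rk4", 0.25), 16, tolerance = 0.15)
})

test_that("outflow limiting drains exactly, scales proportionally and leaves slack flows alone", {
  st <- c(A = 10)
  one <- flow_records("f1", "A", "EXTERNAL", 20)
  expect_equal(limit_outflows(st, one, dt = 1)$value, 10)
  two <- flow_records(c("f1", "f2"), c("A", "A"), c("EXTERNAL", "EXTERNAL"),
                      c(6, 6))
  expect_equal(limit_outflows(st, two, dt = 1)$value, c(5, 5))
  slack <- flow_records("f1", "A", "EXTERNAL", 5)
  expect_equal(limit_outflows(c(A = 100), slack, dt = 1)$value, 5)
  # inflows are untouched even when the source stock is being limited
  mix <- flow_records(c("out", "into"), c("A", "EXTERNAL"), c("EXTERNAL", "A"),
                      c(50, 3))
  lim <- limit_outflows(st, mix, dt = 1)
  expect_equal(lim$value, c(10, 3))
})

test_that("closed subsystems conserve total mass to machine precision per step", {
  params <- closed_params()
  exo <- zero_exogenous()
  state0 <- sadcwc_initial_state()
  for (method in c("euler", "rk4")) {
    tr <- integrate_stocks(
      function(s, t) sadcwc:::sadcwc_flow_values(s, params, exo, t),
      state0, time_grid(2004, 2014, 1 / 12), method = method,
      flows = sadcwc_flow_table())
    total <- rowSums(tr$states[, c("C", "D", "S", "R")])
    expect_lt(max(abs(diff(total))) / total[1], 1e-9)
  }
})

test_that("non-finite flows abort with a diagnostic naming flow and time", {
  fl <- flow_records("bad_flow", "A", "EXTERNAL", NA)
  expect_error(
    integrate_stocks(function(s, t) NaN, c(A = 1), time_grid(2000, 2001, 1),
                     flows = fl),
    "bad_flow")
})

test_that("stocks never go negative under arbitrary non-negative parameter draws", {
  set.seed(2024)
  for (i in 1:200) {
    params <- random_params()
    exo_i <- random_exo()
    st <- random_state()
    tr <- integrate_stocks(
      function(s, t) sadcwc:::sadcwc_flow_values(s, params, exo_i, t),
      st, time_grid(2000, 2003, 1 / 4),
      flows = sadcwc_flow_table())
    expect_true(all(tr$states >= 0))
  }
})

test_that("the unlimited model derivative agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  params <- sadcwc_params()
  exo <- exogenous_flows()
  state0 <- sadcwc_initial_state()
  grid <- time_grid(2004, 2014, 1 / 12)
  ours <- integrate_stocks(
    function(s, t) sadcwc:::sadcwc_flow_values(s, params, exo, t),
    state0, grid, method = "rk4", flows = sadcwc_flow_table(),
    limit = FALSE)
  ref <- deSolve::ode(
    y = state0, times = grid_times(grid),
    func = function(t, y, p) list(derivatives(y, params, exo, t)),
    parms = NULL, method = "rk4")
  final <- ours$states[nrow(ours$states), ]
  expect_equal(final, ref[nrow(ref), names(final)], tolerance = 1e-8)
})

test_that("tidy export reports annual snapshots of stocks and flows", {
  params <- sadcwc_params()
  exo <- exogenous_flows()
  tr <- integrate_stocks(
    function(s, t) sadcwc:::sadcwc_flow_values(s, params, exo, t),
    sadcwc_initial_state(), time_grid(2004, 2006, 1 / 12),
    flows = sadcwc_flow_table())
  td <- as.data.frame(tr)
  expect_setequal(unique(td$year), 2004:2006)
  expect_setequal(unique(td$type), c("stock", "flow"))
  expect_equal(sum(td$type == "stock"), 3 * 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_equal(utils::read.csv(path), td, tolerance = 1e-12)
})
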