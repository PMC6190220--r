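test_that("relaxation response matches its analytic anchors", {
  p <- table1_means("MCF-7")
  # at t = 0 all paths are unrelaxed: y(0) = (k0 + k1 + k2) u
  y0 <- relaxation_response(p, 1, time_grid(0, 0.01, 2))[1]
  expect_equal(y0, 2.984 + 1.110 + 1.385, tolerance = 1e-12)
  # zero input gives zero output at any time
  expect_equal(relaxation_response(p, 0, time_grid(0, 0.5, 10)), rep(0, 10))
  # single path, k0 = k1 = b1 = 1: y(ln 2) = 1 + exp(-ln 2) = 1.5
  p1 <- maxwell_params(1, 1, 1)
  expect_equal(relaxation_response(p1, 1, c(0, log(2)))[2], 1.5, tolerance = 1e-12)
})

test_that("steady-state force is the lone-spring load", {
  expect_equal(steady_state_force(table1_means("MCF-7"), 1), 2.984)
  expect_equal(steady_state_force(table1_means("L-929"), 1), 0.534)
  expect_equal(steady_state_force(table1_means("L-929"), 0), 0)
})

test_that("closed form and state-space integration agree for all cell types", {
  grid <- time_grid(0, 0.002, 3001)
  for (label in cell_population_stats()$label) {
    p <- table1_means(label)
    y_closed <- relaxation_response(p, 1, grid)
    y_rk4 <- simulate_state_space(p, 1, grid)$output
    expect_lt(max(abs(y_rk4 - y_closed) / abs(y_closed)), 1e-6,
              label = sprintf("oracle discrepancy for %s", label))
  }
  # higher orders up to n = 4
  p4 <- maxwell_params(1, c(1, 0.8, 0.6, 0.4), c(0.05, 0.4, 2, 8))
  y_c <- relaxation_response(p4, 1, grid)
  y_i <- simulate_state_space(p4, 1, grid)$output
  expect_lt(max(abs(y_i - y_c) / abs(y_c)), 1e-6)
})

test_that("state-space model honors its fixed points and linearity", {
  p <- table1_means("Neuro-2a")
  grid <- time_grid(0, 0.01, 301)
  # fully relaxed initial state: output constant at k0 u
  traj <- simulate_state_space(p, 2, grid, x_init = rep(2, p$n))
  expect_equal(traj$output, rep(p$k0 * 2, 301), tolerance = 1e-10)
  # zero input, zero state: identically zero
  expect_equal(simulate_state_space(p, 0, grid)$output, rep(0, 301))
  # superposition of two inputs
  t <- grid_times(grid)
  u1 <- pmin(t, 1); u2 <- 0.3 * sin(t)
  y1 <- simulate_state_space(p, u1, grid)$output
  y2 <- simulate_state_space(p, u2, grid)$output
  y12 <- simulate_state_space(p, u1 + u2, grid)$output
  expect_equal(y12, y1 + y2, tolerance = 1e-8)
})

test_that("relaxation is monotone and bounded below by the steady state", {
  for (label in c("MCF-7", "HEK-293")) {
    p <- table1_means(label)
    y <- relaxation_response(p, 1, time_grid(0, 0.01, 601))
    expect_true(all(diff(y) < 0))
    expect_true(all(y > p$k0))
  }
})

test_that("parameter bookkeeping: count, ordering, ties", {
  expect_equal(parameter_count(maxwell_params(1)), 1L)
  expect_equal(parameter_count(table1_means("MCF-7")), 5L)
  expect_equal(parameter_count(maxwell_params(1, c(1, 1, 1), c(1, 2, 3))), 7L)
  # paths sort by ascending tau regardless of input order
  a <- maxwell_params(1, c(1.385, 1.110), c(3.108, 0.118))
  b <- maxwell_params(1, c(1.110, 1.385), c(0.118, 3.108))
  expect_equal(a$k, b$k)
  expect_equal(a$b, b$b)
  # equal tau: tie broken by ascending k
  tie <- maxwell_params(1, c(3, 2), c(3, 2))
  expect_equal(tie$k, c(2, 3))
})

test_that("b = 0 paths decay instantly in the closed form and are rejected by the integrator", {
  p <- maxwell_params(2, c(1, 1), c(0, 1))
  y <- relaxation_response(p, 1, c(0, 0.5, 1))
  expect_equal(y[1], 2 + 1 + 1)
  expect_equal(y[2], 2 + exp(-0.5))
  expect_error(relaxation_response(p, 1, c(-1, 0, 1)), "b = 0")
  expect_error(simulate_state_space(p, 1, time_grid(0, 0.1, 10)), "b > 0")
})

test_that("invalid parameters and grids are rejected", {
  expect_error(maxwell_params(0), "positive")
  expect_error(maxwell_params(1, c(1, -1), c(1, 1)), "positive")
  expect_error(maxwell_params(1, 1, -0.1), "non-negative")
  expect_error(maxwell_params(1, c(1, 2), 1), "same length")
  expect_error(time_grid(0, -0.1, 10), "positive")
  expect_error(relaxation_response(maxwell_params(1, 1, 1), 1, c(0, 0.1, 0.3)),
               "not uniform")
})

test_that("parameters round-trip through the flat config form", {
  p <- table1_means("HEK-293")
  q <- maxwell_from_config(maxwell_to_config(p))
  expect_equal(param_vec(q), param_vec(p), tolerance = 1e-15)
  # and through JSON text
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(maxwell_to_config(p), f, auto_unbox = TRUE, digits = NA)
  q2 <- maxwell_from_config(jsonlite::read_json(f))
  expect_equal(param_vec(q2), param_vec(p), tolerance = 1e-12)
})
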