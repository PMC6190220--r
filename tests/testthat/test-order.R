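test_that("impulse sequence is the first difference of the step response", {
  g <- impulse_from_step(c(5, 4, 3.5, 3.25))
  expect_equal(g$g, c(-1, -0.5, -0.25))
  expect_equal(impulse_from_step(rep(2, 10))$g, rep(0, 9))
  expect_error(impulse_from_step(c(1, 2)), "at least 3")
  # differencing a model curve matches the analytically differenced closed form
  p <- table1_means("MCF-7")
  t <- seq(0, 6, by = 0.01)
  y <- relaxation_response(p, 1, t)
  g2 <- impulse_from_step(y, dt = 0.01)
  analytic <- relaxation_response(p, 1, t + 0.01) - y
  expect_equal(g2$g, analytic[-length(analytic)], tolerance = 1e-12)
})

test_that("Hankel matrices have the anti-diagonal layout", {
  g <- c(1, 2, 3, 4, 5)
  expect_equal(build_hankel(g, 2, 1), matrix(c(1, 2, 2, 3), 2))
  expect_equal(build_hankel(g, 2, 2), matrix(c(2, 3, 3, 4), 2))
  H <- build_hankel(1:9, 3, 2)
  for (r in 1:2) for (c in 1:2)
    expect_equal(H[r, c + 1], H[r + 1, c])  # constant anti-diagonals
  expect_error(build_hankel(g, 2, 4), "'k' must lie")
  expect_error(build_hankel(g, 4, 1), "'k' must lie")
})

test_that("rank law: Hankel determinants collapse above the true order", {
  # noise-free order-2 impulse sequence (two geometric modes)
  i <- 0:40
  g <- 0.7 * 0.8^i + 0.2 * 0.99^i
  d2 <- viscell:::.hankel_dets(g, 2)
  d3 <- viscell:::.hankel_dets(g, 3)
  expect_gt(mean(abs(d2)), 1e-8)
  expect_lt(mean(abs(d3)) / mean(abs(d2)), 1e-10)
  # the l = 3 matrices are singular for every admissible k
  for (k in c(1, 5, 20)) expect_lt(abs(det(build_hankel(g, 3, k))), 1e-12)
})

test_that("Dl statistic: degenerate input, sentinel, and scaling behavior", {
  expect_error(dl_statistic(rep(0, 30), 2), "degenerate")
  i <- 0:40
  g <- 0.7 * 0.8^i + 0.2 * 0.99^i
  d2 <- dl_statistic(g, 2)
  expect_true(is.finite(d2) && d2 > 0)
  # scaling g by c > 0 scales Dl by 1/c (determinants are homogeneous of
  # degree l and l + 1), so the statistic is scale-covariant, not invariant;
  # the argmax is what is scale-free. Checked on a full-rank sequence --
  # round-off-degenerate determinants are not homogeneous.
  set.seed(8)
  gn <- g + rnorm(length(g), sd = 0.05)
  expect_equal(dl_statistic(5 * gn, 2), dl_statistic(gn, 2) / 5, tolerance = 1e-9)
  expect_equal(dl_statistic(5 * gn, 3) / dl_statistic(gn, 3), 1 / 5, tolerance = 1e-9)
})

test_that("order identification recovers known noise-free model orders", {
  t <- seq(0, 6, by = 0.001)
  # second order: MCF-7 means
  y2 <- relaxation_response(table1_means("MCF-7"), 1, t)
  prof2 <- identify_order_curve(y2, fs = 1000)
  expect_identical(prof2$selected_order, 2L)
  expect_identical(prof2$method, "rank-crash")
  # first order: single exponential
  y1 <- relaxation_response(maxwell_params(1, 1, 1), 1, t)
  expect_identical(identify_order_curve(y1, fs = 1000)$selected_order, 1L)
  # third order with well-separated time constants (0.05, 0.5, 5 s)
  p3 <- maxwell_params(1, c(1, 1, 1), c(0.05, 0.5, 5))
  y3 <- relaxation_response(p3, 1, t)
  expect_identical(identify_order_curve(y3, fs = 1000)$selected_order, 3L)
})

test_that("the Dl profile of a clean second-order curve peaks at l = 2 and is censored above", {
  y <- relaxation_response(table1_means("MCF-7"), 1, seq(0, 6, by = 0.001))
  prof <- identify_order_curve(y, fs = 1000, npoints = 200)
  expect_identical(prof$selected_order, 2L)
  dl <- prof$profile$dl
  expect_identical(which.max(ifelse(is.na(dl), -Inf, dl)), 2L)
  expect_true(all(is.na(dl[3:6])))  # round-off junk dimensions excluded
  expect_gt(dl[2], dl[1])
})

test_that("order identification survives measurement noise", {
  p <- table1_means("MCF-7")
  set.seed(101)
  hits <- 0L
  for (r in 1:10) {
    cv <- generate_curve(p, noise_sd = 0.01)
    hits <- hits + (identify_order_curve(cv)$selected_order == 2L)
  }
  expect_gte(hits, 9L)
})

test_that("degenerate and too-short inputs are rejected", {
  expect_error(identify_order(rep(0, 30)), "degenerate")
  expect_error(identify_order(rnorm(8), lmax = 6), "length")
  expect_error(dl_statistic(1:5, 2), "length")
})
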