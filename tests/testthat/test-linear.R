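op <- continuous_params()  # measured operating point

test_that("closed-loop coefficients follow the second-order closed form", {
  expect_equal(unname(closed_loop_coeffs(op)), c(0.8, 4, 4.64))
  unit <- continuous_params(1, 1, 1, 1, 1)
  expect_equal(unname(closed_loop_coeffs(unit)), c(1, 2, 2))
  # complex poles exactly when c > b^2/4
  for (p in list(op, unit)) {
    cc <- closed_loop_coeffs(p)
    expect_true(cc[["c"]] > cc[["b"]]^2 / 4)
  }
  expect_error(continuous_params(p_y = -1), "positive")
})

test_that("steady-state error matches the final-value closed form and is
           monotone in p_yz and p_z", {
  expect_equal(steady_state_error(op), 1.6 / 4.64)
  # feedback strength dominates: error vanishes as p_yz grows
  big <- continuous_params(p_yz = 1e9)
  expect_lt(steady_state_error(big), 1e-8)
  grid <- seq(0.5, 3, length.out = 20)
  for (v in seq(0.5, 3, length.out = 20)) {
    e_yz <- vapply(grid, function(g)
      steady_state_error(continuous_params(p_yz = g, p_z = v)), 0)
    e_z <- vapply(grid, function(g)
      steady_state_error(continuous_params(p_z = g, p_yz = v)), 0)
    expect_true(all(diff(e_yz) < 0))
    expect_true(all(diff(e_z) < 0))
  }
})

test_that("natural frequency and damping ratio evaluate and behave correctly", {
  expect_equal(natural_frequency(op), sqrt(4.64))
  expect_equal(damping_ratio(op), 4 / (2 * sqrt(4.64)))
  # weak-coupling limit of a symmetric cascade is critically damped
  weak <- continuous_params(p_zy = 1e-9, p_yz = 1e-9, p_y = 2, p_z = 2)
  expect_equal(damping_ratio(weak), 1, tolerance = 1e-9)
  z <- vapply(seq(0.5, 3, length.out = 20), function(g)
    damping_ratio(continuous_params(p_yz = g)), 0)
  expect_true(all(diff(z) < 0))
})

test_that("percent overshoot: exact endpoints, monotone continuous decay", {
  expect_identical(percent_overshoot(0), 100)
  expect_equal(percent_overshoot(damping_ratio(op)), 0.0388, tolerance = 1e-2)
  expect_identical(percent_overshoot(1), 0)
  expect_identical(percent_overshoot(2.5), 0)
  zg <- seq(0, 0.999, length.out = 400)
  os <- percent_overshoot(zg)
  expect_true(all(diff(os) < 0))
  expect_true(all(abs(diff(os)) < 2))  # no jumps: continuity at this grid scale
  expect_error(percent_overshoot(-0.1), "zeta")
})

test_that("zeta-minimizing p_z matches the stationarity condition", {
  res <- zeta_minimizing_pz(op)
  expect_true(res$interior)
  expect_equal(res$p_z_min, 1.36)
  # boundary case p_y^2 = 2 p_yz p_zy
  bnd <- continuous_params(p_yz = 2, p_zy = 1, p_y = 2)
  expect_equal(zeta_minimizing_pz(bnd)$p_z_min, 0)
  expect_false(zeta_minimizing_pz(bnd)$interior)
  # no interior minimum when coupling dominates
  none <- continuous_params(p_yz = 3, p_zy = 3, p_y = 1)
  expect_true(is.na(zeta_minimizing_pz(none)$p_z_min))
  # central-difference oracle: d zeta / d p_z flips sign exactly at p_z_min
  h <- 1e-6
  dzeta <- function(pz) {
    f <- function(v) damping_ratio(continuous_params(p_z = v))
    (f(pz + h) - f(pz - h)) / (2 * h)
  }
  expect_lt(dzeta(1.36 - 0.01), 0)
  expect_gt(dzeta(1.36 + 0.01), 0)
  expect_equal(dzeta(1.36), 0, tolerance = 1e-5)
})

test_that("open-loop p53 step response: amplitude scales with p_yz,
           response time does not", {
  tgrid <- seq(0, 5, by = 0.01)
  r <- step_response_p53(op, Y = 1, times = tgrid)
  expect_equal(r$response_time, log(2) / 2)
  expect_equal(r$amplitude, 0.4)
  expect_equal(r$sign, -1)
  r2 <- step_response_p53(continuous_params(p_yz = 1.6), Y = 1, times = tgrid)
  expect_equal(r2$response_time, r$response_time)
  expect_equal(r2$amplitude, 2 * r$amplitude)
  # trajectory actually crosses half amplitude at the response time
  i <- which.min(abs(tgrid - r$response_time))
  expect_equal(r$z[i], r$amplitude / 2, tolerance = 1e-2)
  expect_error(step_response_p53(op, Y = 1, times = numeric(0)), "non-empty")
})

test_that("second-order step response reproduces the overshoot formula", {
  tg <- seq(0, 60, length.out = 20001)
  crit <- second_order_step_response(1, 1, tg)
  expect_true(all(diff(crit$y) >= -1e-12))
  expect_equal(crit$empirical_os, 0)
  und <- second_order_step_response(1, 0.2, tg)
  expect_equal(max(und$y), 1 + percent_overshoot(0.2) / 100, tolerance = 5e-3)
  osc <- second_order_step_response(1, 0, tg)
  expect_equal(max(osc$y), 2, tolerance = 1e-6)
  expect_equal(mean(osc$y), 1, tolerance = 1e-2)
  for (z in seq(0.1, 0.9, by = 0.1)) {
    emp <- second_order_step_response(2, z, tg)$empirical_os
    expect_equal(emp, percent_overshoot(z), tolerance = 5e-3)
  }
  over <- second_order_step_response(1, 2, tg)
  expect_equal(over$empirical_os, 0)
  expect_equal(over$y[length(tg)], 1, tolerance = 1e-6)
})

test_that("trade-off sweeps show the published shapes", {
  sw <- tradeoff_sweep(op, "p_yz")
  expect_true(all(diff(sw$ss_error) < 0))
  expect_true(all(diff(sw$percent_os) >= 0))
  swz <- tradeoff_sweep(op, "p_z", grid = seq(0.5, 3, length.out = 101))
  peak <- swz$param_value[which.max(swz$percent_os)]
  expect_equal(peak, 1.36, tolerance = 0.03)
  # error still falls monotonically along the p_z axis
  expect_true(all(diff(swz$ss_error) < 0))
  one <- tradeoff_sweep(op, "p_yz", grid = 0.8)
  expect_equal(one$ss_error, steady_state_error(op))
  expect_equal(one$percent_os, percent_overshoot(damping_ratio(op)))
  expect_error(tradeoff_sweep(op, "p_yz", grid = c(2, 1)), "increasing")
})

test_that("second-order summary bundles the four metrics coherently", {
  s <- summary(op)
  expect_s3_class(s, "second_order_summary")
  expect_equal(s$zeta, damping_ratio(op))
  expect_equal(s$ss_error, steady_state_error(op))
  expect_equal(s$percent_os, percent_overshoot(s$zeta))
})
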