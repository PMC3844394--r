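test_that("summed reaction drift reproduces the deterministic rates", {
  p <- mech_params(gamma = 2.5)
  sys <- build_reaction_system(p)
  set.seed(41)
  for (i in 1:20) {
    st <- runif(4, 0, 50)
    drift <- colSums(sys$stoich * sys$propensities(st))
    rhs <- p53loop:::mech_rhs_core(
      stats::setNames(st, sys$species), p,
      m1_lag = st[1], m3_lag = st[3])
    expect_equal(unname(drift), unname(rhs), tolerance = 1e-12)
  }
  # Hill and MM propensities vanish without p53 and saturate above K1
  a0 <- sys$propensities(c(5, 5, 5, 0))
  expect_equal(a0[1], 0)
  expect_equal(a0[9], 0)
  asat <- sys$propensities(c(0, 0, 0, 1e9))
  expect_equal(asat[1], p$beta1, tolerance = 1e-6)
})

test_that("pure death process matches its exponential mean decay", {
  p <- mech_params(beta1 = 1e-12, beta2 = 1e-12, beta3 = 1e-12,
                   beta4 = 1e-12, alpha4 = 0.01, gamma = 1e-12)
  sys <- build_reaction_system(p)
  fin <- vapply(1:500, function(r)
    gillespie_run(sys, c(0, 0, 0, 100), t_end = 50, seed = r,
                  record_times = 50)$p53, 0)
  expected <- 100 * exp(-0.5)
  sem <- stats::sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - expected), 3 * sem)
})

test_that("birth-death process reaches the Poisson stationary law", {
  p <- mech_params(beta1 = 1e-12, beta2 = 1e-12, beta3 = 1e-12,
                   alpha3 = 1e-12, beta4 = 5, alpha4 = 0.5, gamma = 1e-12)
  sys <- build_reaction_system(p)
  st <- ensemble_steady_stats(sys, c(0, 0, 1, 0), n_runs = 300, t_end = 40,
                              burn_in = 20, seed = 7)
  expect_equal(st$mean, 10, tolerance = 0.05)
  expect_equal(st$noise, 1, tolerance = 0.1)
  # doubling the ensemble moves the mean by less than 2 pooled SEMs
  st2 <- ensemble_steady_stats(sys, c(0, 0, 1, 0), n_runs = 600, t_end = 40,
                               burn_in = 20, seed = 1007)
  sem <- sqrt(st$variance / st$n_runs + st2$variance / st2$n_runs)
  expect_lt(abs(st$mean - st2$mean), 2 * sem)
})

test_that("compiled and reference SSA engines agree statistically", {
  p <- mech_params(beta1 = 1e-12, beta2 = 1e-12, beta3 = 1e-12,
                   alpha3 = 1e-12, beta4 = 5, alpha4 = 0.5, gamma = 1e-12)
  sys <- build_reaction_system(p)
  rt <- seq(20, 40, length.out = 10)
  mr <- vapply(1:150, function(r)
    mean(gillespie_run(sys, c(0, 0, 1, 0), 40, seed = r,
                       record_times = rt, engine = "R")$p53), 0)
  mc <- vapply(1:150, function(r)
    mean(gillespie_run(sys, c(0, 0, 1, 0), 40, seed = r + 999,
                       record_times = rt)$p53), 0)
  expect_gt(stats::t.test(mr, mc)$p.value, 0.001)
})

test_that("trajectories are seed-reproducible and seed-sensitive", {
  sys <- build_reaction_system(mech_params(gamma = 1), omega = 5)
  init <- round(mech_steady_state(mech_params(gamma = 1)) * 5)
  rt <- seq(0, 50, by = 5)
  a <- gillespie_run(sys, init, 50, seed = 13, record_times = rt)
  b <- gillespie_run(sys, init, 50, seed = 13, record_times = rt)
  c2 <- gillespie_run(sys, init, 50, seed = 14, record_times = rt)
  expect_identical(a, b)
  expect_false(identical(a$p53, c2$p53))
})

test_that("full-model SSA fluctuates around the deterministic steady state", {
  p <- mech_params(gamma = 1)
  ss <- mech_steady_state(p)
  sys <- build_reaction_system(p, omega = 10)
  st <- ensemble_steady_stats(sys, round(ss * 10), n_runs = 100,
                              t_end = 900, burn_in = 500, seed = 3)
  sem_between <- stats::sd(st$run_means) / sqrt(st$n_runs)
  expect_lt(abs(st$mean - ss[["p53"]] * 10), 3 * sem_between + 0.5)
})

test_that("alpha4 compensation holds the p53 level at the target", {
  p <- mech_params()
  # gamma -> 0 limit collapses to the linear closed form
  a4 <- compensate_alpha4(p, gamma = 1e-12, target = 20)
  expect_equal(a4, p$beta4 * (p$beta3 / p$alpha3) / 20, tolerance = 1e-9)
  gs <- c(0.5, 1, 2, 4, 8)
  a4s <- vapply(gs, function(g) compensate_alpha4(p, g, target = 2), 0)
  expect_true(all(diff(a4s) < 0))
  # forward-simulation oracle: compensated model settles at the target
  q <- p
  q$gamma <- 3
  q$alpha4 <- compensate_alpha4(p, 3, target = 2)
  expect_equal(mech_steady_state(q)[["p53"]], 2, tolerance = 0.01)
  tr <- simulate_mech(q, c(0, 0, 0, 0), t_end = 2500)
  expect_equal(tr$p53[nrow(tr)], 2, tolerance = 0.01)
  expect_error(compensate_alpha4(p, gamma = 1e4, target = 50), "positive")
})

test_that("a single-gamma noise table matches a direct ensemble call", {
  ns <- noise_vs_gamma(mech_params(), gamma_grid = 5, target = 2,
                       n_runs = 40, t_end = 700, burn_in = 400,
                       seed = 17, omega = 5)
  q <- mech_params()
  q$gamma <- 5
  q$alpha4 <- compensate_alpha4(mech_params(), 5, 2)
  sys <- build_reaction_system(q, omega = 5)
  st <- ensemble_steady_stats(sys, round(mech_steady_state(q) * 5),
                              n_runs = 40, t_end = 700, burn_in = 400,
                              seed = 17)
  expect_equal(ns$mean, st$mean)
  expect_equal(ns$noise, st$noise)
})
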