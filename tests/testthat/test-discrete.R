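dna <- discrete_params()  # DNA-damage condition means

test_that("discrete simulation iterates the difference equations", {
  z0 <- suppressWarnings(discrete_params(0, 0, 0, 0, 0))
  s <- simulate_discrete(z0, c(x = 2, y = 3, z = 4), 5)
  expect_equal(s$y[-1], rep(0, 5))
  expect_equal(s$z[-1], rep(0, 5))
  id <- suppressWarnings(discrete_params(w_xy = 0, w_zy = 0, w_yz = 0,
                                         w_y = 1, w_z = 1))
  s2 <- simulate_discrete(id, c(x = 1, y = 2, z = 3), 10)
  expect_equal(s2$y, rep(2, 11))
  expect_equal(s2$z, rep(3, 11))
  one <- simulate_discrete(dna, c(x = 0, y = 0, z = 1), 1)
  expect_equal(one$y[2], 0.2662)
})

test_that("discrete steady-state error matches the final-value closed form", {
  expect_equal(dt_steady_state_error(dna),
               0.2662 * (1 - 0.8737) /
                 ((1 - 0.8737) * (1 - 0.3627) + 0.1656 * 0.2662))
  expect_equal(dt_steady_state_error(dna), 0.2699, tolerance = 1e-3)
  expect_equal(dt_steady_state_error(discrete_params(w_zy = 0)), 0)
  # decreasing in w_yz, increasing in w_z
  e <- vapply(seq(0.05, 0.9, length.out = 15), function(v)
    dt_steady_state_error(discrete_params(w_yz = v)), 0)
  expect_true(all(diff(e) < 0))
  e2 <- vapply(seq(0.05, 0.9, length.out = 15), function(v)
    dt_steady_state_error(discrete_params(w_z = v)), 0)
  expect_true(all(diff(e2) > 0))
})

test_that("Euler substitution makes discrete and continuous errors identical", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_cparams()
    for (T in c(0.01, 0.11, 0.5)) {
      expect_equal(dt_steady_state_error(euler_weights(p, T)),
                   steady_state_error(p), tolerance = 1e-12)
    }
  }
})

test_that("z-domain coefficients and poles are mutually consistent", {
  cc <- dt_closed_loop_coeffs(dna)
  expect_equal(unname(cc),
               c(0.1656, -1.2364, 0.8737 * 0.3627 + 0.1656 * 0.2662))
  z0 <- suppressWarnings(discrete_params(0, 0, 0, 0, 0))
  expect_equal(unname(dt_closed_loop_coeffs(z0)), c(0, 0, 0))
  # roots of the characteristic polynomial satisfy it
  ps <- char_poles(dna)
  for (i in 1:2) {
    pole <- complex(real = ps$re[i], imaginary = ps$im[i])
    expect_equal(Mod(pole^2 + cc[["b"]] * pole + cc[["c"]]), 0,
                 tolerance = 1e-12)
  }
})

test_that("characteristic poles match hand-computed values", {
  ps <- char_poles(dna)
  expect_equal(sort(ps$re), c(0.4726, 0.7638), tolerance = 1e-4)
  expect_equal(ps$im, c(0, 0))
  expect_equal(ps$zeta, c(1, 1))
  # stronger feedback pushes the pair complex
  ps2 <- char_poles(discrete_params(w_yz = 0.6708))
  expect_true(all(ps2$im != 0))
  expect_equal(ps2$magnitude, rep(0.7039, 2), tolerance = 1e-4)
  expect_equal(ps2$zeta, rep(0.576, 2), tolerance = 1e-3)
  dbl <- suppressWarnings(discrete_params(w_zy = 0, w_yz = 0,
                                          w_y = 0.6, w_z = 0.6))
  expect_equal(char_poles(dbl)$re, c(0.6, 0.6))
})

test_that("pole-to-damping mapping covers real, complex and boundary poles", {
  expect_equal(pole_to_damping(0.7637)[["zeta"]], 1)
  expect_equal(pole_to_damping(complex(modulus = 1, argument = 0.3))[["zeta"]],
               0)
  neg <- pole_to_damping(-0.5)
  expect_equal(neg[["zeta"]], abs(log(0.5)) / sqrt(log(0.5)^2 + pi^2))
  expect_error(pole_to_damping(0), "origin")
  # zeta does not depend on the sampling period; omega_n scales with 1/T
  a <- pole_to_damping(complex(real = 0.6, imaginary = 0.3), T = 0.11)
  b <- pole_to_damping(complex(real = 0.6, imaginary = 0.3), T = 0.5)
  expect_equal(a[["zeta"]], b[["zeta"]])
  expect_equal(a[["omega_n"]] * 0.11, b[["omega_n"]] * 0.5)
  # property: inside the closed unit disk zeta is in [0, 1], and zeta = 1
  # only for positive real poles
  set.seed(21)
  for (i in 1:200) {
    p <- complex(modulus = stats::runif(1, 0.05, 1),
                 argument = stats::runif(1, -pi, pi))
    zt <- pole_to_damping(p)[["zeta"]]
    expect_gte(zt, 0)
    expect_lte(zt, 1)
    if (abs(Arg(p)) > 1e-12 || Mod(p) >= 1) expect_lt(zt, 1)
  }
})

test_that("sustained disturbance on the p53 update converges to the
           final-value prediction", {
  s <- simulate_discrete(dna, c(x = 0, y = 0, z = 0), 400, disturbance = 1)
  err <- dna$w_zy * s$z[401]
  expect_equal(err, dt_steady_state_error(dna), tolerance = 1e-6)
})

test_that("Monte-Carlo pole ensembles reproduce the condition contrasts", {
  d <- dna_damage_distribution()
  # degenerate distribution collapses onto the mean-parameter poles
  d0 <- param_distribution(mean = d$mean, sd = d$sd * 0)
  pe0 <- monte_carlo_poles(d0, n_samples = 10, seed = 1)
  expect_equal(unique(round(pe0$poles$re, 10)),
               round(char_poles(dna)$re, 10))
  pe <- monte_carlo_poles(d, n_samples = 100, seed = 3)
  expect_gte(pe$zeta_summary[["median"]], 0.8)
  tr <- scale_condition(d, w_yz_mean = 0.6708)
  pet <- monte_carlo_poles(tr, n_samples = 100, seed = 3)
  expect_lte(pet$zeta_summary[["median"]], 0.8)
  # post-translational scaling restores damping relative to transcriptional
  pt <- scale_condition(d, 3.67, "post_translational")
  pep <- monte_carlo_poles(pt, n_samples = 100, seed = 3)
  expect_gt(pep$zeta_summary[["median"]], pet$zeta_summary[["median"]])
  # reproducible under the same seed
  expect_identical(monte_carlo_poles(d, 50, seed = 9)$poles,
                   monte_carlo_poles(d, 50, seed = 9)$poles)
  # summary stabilises as the ensemble grows
  m1 <- monte_carlo_poles(tr, 400, seed = 5)$zeta_summary[["median"]]
  m2 <- monte_carlo_poles(tr, 800, seed = 6)$zeta_summary[["median"]]
  expect_lt(abs(m1 - m2), 0.05)
})

test_that("condition scaling follows the fold arithmetic with SDs fixed", {
  d <- dna_damage_distribution()
  expect_equal(scale_condition(d, 1)$mean, d$mean)
  tr <- scale_condition(d, 3.67, "transcriptional")
  expect_equal(tr$mean[["w_yz"]], 0.1656 * 3.67)
  expect_equal(tr$mean[["w_z"]], d$mean[["w_z"]])
  pt <- scale_condition(d, 3.67, "post_translational")
  expect_equal(pt$mean[["w_yz"]], 0.1656 * 3.67)
  expect_equal(pt$mean[["w_z"]], 0.3627 / 3.67)
  expect_equal(pt$sd, d$sd)
  ov <- scale_condition(d, 3.67, "post_translational",
                        w_yz_mean = 0.6708, w_z_mean = 0.0998)
  expect_equal(ov$mean[["w_yz"]], 0.6708)
  expect_equal(ov$mean[["w_z"]], 0.0998)
})
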