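magic <- 180 / pi * acos(sqrt(1 / 3))  # 54.7356...

test_that("the classical dipole term vanishes at the magic angle", {
  root <- uniroot(function(t) 3 * cos(t * pi / 180)^2 - 1, c(40, 70),
                  tol = 1e-12)$root
  expect_equal(root, 54.7356, tolerance = 1e-4)
  expect_equal(model_eval("classical_dipole", c(a = 0, b = 5), root), 0,
               tolerance = 1e-10)
  expect_equal(model_eval("extended_dipole", c(a = 0, b = 5), root), 0,
               tolerance = 1e-10)
  # and it is a minimum: values rise on either side
  expect_gt(model_eval("classical_dipole", c(a = 0, b = 5), root - 10), 0)
  expect_gt(model_eval("classical_dipole", c(a = 0, b = 5), root + 10), 0)
})

test_that("the RDC kernel matches its azimuthal quadrature identity", {
  expect_equal(gen_mae_f(0, 0), 4)
  expect_equal(gen_mae_f(90, 90), 11 / 8)
  grid <- seq(0, 90, length.out = 50)
  phi <- (seq_len(720) - 0.5) * (2 * pi / 720)
  worst <- 0
  for (a in grid) for (e in grid) {
    ct <- cos(a * pi / 180) * cos(e * pi / 180) -
      sin(a * pi / 180) * sin(e * pi / 180) * cos(phi)
    worst <- max(worst, abs(gen_mae_f(a, e) - mean((3 * ct^2 - 1)^2)))
  }
  expect_lt(worst, 1e-10)
  # symmetry in its two angles
  expect_equal(gen_mae_f(grid, rev(grid)), gen_mae_f(rev(grid), grid))
})

test_that("extended dipole nests inside the generalized MAE model", {
  th <- seq(0, 90, by = 3)
  expect_equal(model_eval("extended_dipole", c(a = 2, b = 1.5), th),
               model_eval("gen_mae", c(p_i = 2, p_a = 1.5, alpha = 0,
                                       eps0 = 0), th),
               tolerance = 1e-12)
})

test_that("noiseless self-fits of the linear models are exact", {
  th <- seq(1.25, 88.75, by = 2.5)
  cases <- list(
    list(id = "susceptibility", p = c(a = 20.04, b = 0.03, c = 3.07)),
    list(id = "susceptibility", p = c(a = 42.00, b = -10.43, c = 20.72)),
    list(id = "classical_dipole", p = c(a = 21.72, b = -1.03)),
    list(id = "extended_dipole", p = c(a = 21.95, b = -0.54)))
  for (cs in cases) {
    y <- model_eval(cs$id, cs$p, th)
    f <- fit_model(tibble::tibble(angle_mid = th, mean = y, n = 1), cs$id)
    expect_equal(unname(f$params), unname(cs$p), tolerance = 1e-8)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("gen-MAE round trip recovers the in-vivo-scale R2 parameters", {
  th <- seq(1.25, 88.75, by = 2.5)
  truth <- c(p_i = 17.64, p_a = 5.99, alpha = 69.15, eps0 = 17.99)
  y <- model_eval("gen_mae", truth, th)
  f <- fit_model(tibble::tibble(angle_mid = th, mean = y, n = 1),
                 "gen_mae", target = "R2")
  expect_equal(unname(f$params), unname(truth), tolerance = 1e-3)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # offset-corrected variant on the epsilon axis
  y2 <- model_eval("gen_mae_eps0corr", truth[1:3], th)
  f2 <- fit_model(tibble::tibble(angle_mid = th, mean = y2, n = 1),
                  "gen_mae_eps0corr", target = "R2")
  expect_equal(unname(f2$params), unname(truth[1:3]), tolerance = 1e-3)
  # fixing eps0 removes it from the optimization but keeps it in the curve
  y3 <- model_eval("gen_mae", c(truth[1:3], eps0 = 0), th)
  f3 <- fit_model(tibble::tibble(angle_mid = th, mean = y3, n = 1),
                  "gen_mae", target = "R2", fix = list(eps0 = 0))
  expect_equal(unname(f3$params[1:3]), unname(truth[1:3]), tolerance = 1e-3)
})

test_that("unconstrained AI fits land on an exactly equivalent curve", {
  # for the asymmetry index, (p_i, p_a, alpha) is identifiable only up to an
  # exact two-branch conjugacy (f(alpha, .) spans quadratics in sin^2);
  # the fit must reproduce the curve even if it reports the conjugate branch
  th <- seq(1.25, 88.75, by = 2.5)
  truth <- c(p_i = -0.03, p_a = 0.12, alpha = 68.9)
  y <- model_eval("gen_mae_eps0corr", truth, th)
  f <- fit_model(tibble::tibble(angle_mid = th, mean = y, n = 1),
                 "gen_mae_eps0corr", target = "AI")
  expect_equal(predict(f), y, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
})

test_that("seeded noisy recovery of the sin^4 coefficient is accurate", {
  th <- seq(1.25, 88.75, by = 2.5)
  truth <- c(a = 20.04, b = 0.03, c = 3.07)
  y0 <- model_eval("susceptibility", truth, th)
  set.seed(1234)
  errs <- replicate(200, {
    f <- fit_model(tibble::tibble(angle_mid = th,
                                  mean = y0 + rnorm(length(th), 0, 0.1),
                                  n = 1), "susceptibility")
    abs(f$params[["c"]] - truth[["c"]])
  })
  expect_lt(median(errs), 0.15)
})

test_that("gen-MAE bounds are honoured", {
  th <- seq(2.5, 87.5, by = 5)
  y <- model_eval("gen_mae", c(p_i = 17, p_a = 6, alpha = 70, eps0 = 18), th)
  f <- fit_model(tibble::tibble(angle_mid = th, mean = y, n = 1),
                 "gen_mae", target = "R2")
  p <- f$params
  expect_true(p[["p_i"]] >= 0 && p[["p_i"]] <= 100)
  expect_true(p[["p_a"]] >= 0 && p[["p_a"]] <= 50)
  expect_true(p[["alpha"]] >= 0 && p[["alpha"]] <= 90)
  expect_true(p[["eps0"]] >= 0 && p[["eps0"]] <= 45)
})

test_that("R^2 is undefined for constant data and fits fail when underdetermined", {
  th <- seq(0, 90, by = 10)
  f <- fit_model(tibble::tibble(angle_mid = th, mean = 5, n = 1),
                 "classical_dipole")
  expect_true(is.na(f$r_squared))
  expect_error(fit_model(tibble::tibble(angle_mid = c(10, 20), mean = c(1, 2),
                                        n = 1), "susceptibility"), "fewer")
})

test_that("susceptibility partition reproduces the printed worked arithmetic", {
  p1 <- susceptibility_partition(5.99, 28.30, 10.56)
  expect_equal(round(p1$pct_low, 1), 39.0)
  expect_equal(round(p1$pct_high, 1), 87.1)
  expect_equal(round(p1$ratio, 1), 4.7)
  p2 <- susceptibility_partition(8.58, 28.30, 10.56)
  expect_equal(round(p2$pct_low, 1), 24.0)
  expect_equal(round(p2$pct_high, 1), 77.0)
  expect_equal(round(p2$ratio, 1), 3.3)
  # no field dependence -> pure magic angle limit
  p3 <- susceptibility_partition(5, 5)
  expect_equal(p3$pct_low, 0)
  expect_equal(p3$pct_high, 0)
  expect_equal(p3$ratio, 1)
  expect_equal(field_ratio_eta(), (9.39 / 2.89)^2)
  expect_equal(round(field_ratio_eta(), 2), 10.56)
})

test_that("profile periodicity follows 1/(gamma_bar |dchi| B0)", {
  expect_equal(round(1e3 * bssfp_profile_period(0.1, 2.89)), 81)
  expect_equal(round(1e3 * bssfp_profile_period(0.1, 9.39)), 25)
  expect_equal(bssfp_profile_period(0.2, 2.89),
               bssfp_profile_period(0.1, 2.89) / 2)
  expect_error(bssfp_profile_period(0, 3), "non-zero")
})
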