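test_that("steady state matches the on-resonance closed form across flip angles", {
  sq <- seq_params()
  for (tt in list(c(1, 0.060), c(0.3, 0.012), c(1.5, 0.030), c(0.4, 0.010))) {
    tis <- tissue_table(T1 = tt[1], T2 = tt[2])
    E1 <- exp(-sq$TR / tt[1]); E2 <- exp(-sq$TR / tt[2])
    for (flip in c(1, 5, 15, 40, 80)) {
      sqf <- seq_params(flip_nominal = flip)
      a <- flip * pi / 180
      closed <- sin(a) * (1 - E1) * sqrt(E2) /
        (1 - (E1 - E2) * cos(a) - E1 * E2)
      s <- steady_state_signal(sqf, tis, pi)
      expect_equal(Mod(s), closed, tolerance = 1e-10)
    }
  }
})

test_that("closed-form solve agrees with the iterated recursion off resonance", {
  sq <- seq_params()
  tis <- tissue_table(T1 = 1, T2 = 0.06, freq_offset = 37)
  for (phi in c(0.3, pi / 2, pi, 5)) {
    expect_equal(steady_state_signal(sq, tis, phi),
                 steady_state_signal(sq, tis, phi, method = "iterate"),
                 tolerance = 1e-9)
  }
})

test_that("zero excitation gives zero signal and the profile is 1/TR-periodic", {
  tis <- tissue_table(T1 = 1, T2 = 0.06)
  expect_equal(Mod(steady_state_signal(seq_params(flip_nominal = 0 + 1e-300),
                                       tis, pi)), 0, tolerance = 1e-200)
  # shifting the off-resonance by 1/TR reproduces the steady state (the
  # readout at TE picks up a pure global phase exp(i*2*pi*TE/TR))
  sq <- seq_params()
  s0 <- steady_state_signal(sq, tis, 1.1)
  tis2 <- tissue_table(T1 = 1, T2 = 0.06, freq_offset = 1 / sq$TR)
  s1 <- steady_state_signal(sq, tis2, 1.1)
  expect_equal(Mod(s1), Mod(s0), tolerance = 1e-12)
  expect_equal(s1, s0 * exp(2i * pi * sq$TE / sq$TR), tolerance = 1e-12)
})

test_that("configuration modes implement the DFT with the fixed sign convention", {
  sq <- seq_params()
  prof <- simulate_profile(tissue_table(T1 = 1, T2 = 0.06), sq)
  # constant profile: all weight in F_0
  pc <- prof; pc$signal <- rep(2 + 1i, 12)
  md <- configuration_modes(pc)
  expect_equal(md$F_0, 2 + 1i, tolerance = 1e-12)
  expect_equal(Mod(md$F_minus1), 0, tolerance = 1e-12)
  expect_equal(Mod(md$F_plus1), 0, tolerance = 1e-12)
  # single positive harmonic lands on F_plus1
  ph <- prof; ph$signal <- exp(1i * prof$phase_increment)
  mh <- configuration_modes(ph)
  expect_equal(mh$F_plus1, 1 + 0i, tolerance = 1e-12)
  expect_equal(Mod(mh$F_0) + Mod(mh$F_minus1), 0, tolerance = 1e-12)
  # linearity in the profile
  p2 <- prof; p2$signal <- 3 * prof$signal + (1 - 2i) * pc$signal
  m1 <- configuration_modes(prof)
  m2 <- configuration_modes(p2)
  expect_equal(m2$F_0, 3 * m1$F_0 + (1 - 2i) * (2 + 1i), tolerance = 1e-12)
  expect_equal(m2$F_plus1, 3 * m1$F_plus1, tolerance = 1e-12)
})

test_that("12-point modes agree with a dense quadrature of the frequency response", {
  sq <- seq_params()
  tis <- tissue_table(T1 = 1, T2 = 0.06)
  md12 <- configuration_modes(simulate_profile(tis, sq))
  phi_dense <- (seq_len(4096) - 0.5) * (2 * pi / 4096)
  sig <- vapply(phi_dense, function(p)
    steady_state_signal(sq, tis, p), complex(1))
  dense <- function(n) sum(sig * exp(-1i * n * phi_dense)) / 4096
  scale <- Mod(dense(0))
  expect_lt(Mod(md12$F_minus1 - dense(-1)) / scale, 1e-3)
  expect_lt(Mod(md12$F_0 - dense(0)) / scale, 1e-3)
  expect_lt(Mod(md12$F_plus1 - dense(1)) / scale, 1e-3)
})

test_that("mode extraction rejects degenerate inputs", {
  sq <- seq_params()
  prof <- simulate_profile(tissue_table(T1 = 1, T2 = 0.06), sq)
  bad <- prof[c(1, 2, 4, 5, 6, 7, 8, 9, 10, 11, 12), ]  # non-uniform spacing
  expect_error(configuration_modes(bad), "uniformly")
  expect_error(configuration_modes(prof[1:2, ]), "at least 3")
})

test_that("single-pool and mirror-symmetric profiles have zero asymmetry", {
  sq <- seq_params()
  ai1 <- asymmetry_index(simulate_profile(tissue_table(T1 = 1, T2 = 0.06), sq))
  expect_equal(ai1$AI, 0, tolerance = 1e-10)
  # two pools at opposite offsets, equal weights: magnitude is mirror-symmetric
  tis <- tissue_table(compartment = c("a", "b"), T1 = 1, T2 = 0.06,
                      pd = 1, freq_offset = c(20, -20))
  ai2 <- asymmetry_index(simulate_profile(tis, sq))
  expect_equal(ai2$AI, 0, tolerance = 1e-10)
})

test_that("asymmetry index follows its definition and detects a shifted myelin pool", {
  sq <- seq_params()
  # AI = (h_p - h_n)/(h_p + h_n) on the returned peak heights
  tis <- tissue_table(compartment = c("water", "myelin"),
                      T1 = c(1, 0.3), T2 = c(0.06, 0.012), pd = c(1, 0.5),
                      freq_offset = c(0, 0))
  base <- asymmetry_index(simulate_profile(tis, sq))
  expect_equal(base$AI, (base$h_p - base$h_n) / (base$h_p + base$h_n))
  expect_lt(abs(base$AI), 1e-6)  # parallel fibers: no myelin shift
  # perpendicular fibers: myelin water shifted by the hollow-cylinder interior
  # offset -delta_chi/6 at 3T (delta_chi = -0.1 ppm)
  shift_hz <- 0.1e-6 / 6 * 42.577e6 * 2.89
  tis$freq_offset <- c(0, shift_hz)
  perp <- asymmetry_index(simulate_profile(tis, sq))
  expect_gt(abs(perp$AI), abs(base$AI) + 1e-5)
})

test_that("AI and mode magnitudes are invariant to a global complex phase", {
  sq <- seq_params()
  tis <- tissue_table(compartment = c("w", "m"), T1 = c(1, 0.3),
                      T2 = c(0.06, 0.012), pd = c(1, 0.5),
                      freq_offset = c(0, 3))
  prof <- simulate_profile(tis, sq)
  rot <- prof; rot$signal <- prof$signal * exp(1i * 1.234)
  expect_equal(asymmetry_index(rot)$AI, asymmetry_index(prof)$AI,
               tolerance = 1e-12)
  expect_equal(Mod(unlist(configuration_modes(rot))),
               Mod(unlist(configuration_modes(prof))), tolerance = 1e-12)
})

test_that("a flat profile yields AI = 0 with a warning flag", {
  sq <- seq_params()
  prof <- simulate_profile(tissue_table(T1 = 1, T2 = 0.06), sq)
  prof$signal <- rep(1 + 0i, 12)
  expect_warning(ai <- asymmetry_index(prof), "flat")
  expect_identical(ai$AI, 0)
  expect_true(ai$flat)
})

test_that("three-compartment profile is more asymmetric perpendicular than parallel", {
  sq <- seq_params()
  t3 <- wm_compartments("3T")
  # hollow-cylinder interior offsets: 0 at theta = 0, -delta_chi/6 at 90 deg
  shift90 <- 0.1e-6 / 6 * 42.577e6 * 2.89
  t_par <- t3
  t_perp <- t3; t_perp$freq_offset[3] <- shift90
  ai_par <- asymmetry_index(simulate_profile(t_par, sq))$AI
  ai_perp <- asymmetry_index(simulate_profile(t_perp, sq))$AI
  expect_gt(abs(ai_perp), abs(ai_par))
})
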