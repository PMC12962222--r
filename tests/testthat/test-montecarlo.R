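test_that("stationary spins accumulate exactly the local per-TR phase", {
  tis <- wm_compartments("3T"); tis$D <- 0
  sub <- uniform_substrate(40, tissues = tis)
  sq <- seq_params(n_dummy = 2)
  f0 <- 40  # Hz at 2.89 T
  fm <- field_map(sub, 0, delta_chi = 0)
  fm$offset <- matrix(f0 / (42.577e6 * 2.89), 40, 40)
  wk <- walk_spins(sub, sq, list(fm), walk_config(n_spins = 120, seed = 3))
  expect_equal(max(abs(wk$phase_te - 2 * pi * 42.577e6 * fm$offset[1] * sq$TE)),
               0, tolerance = 1e-14)
  expect_equal(max(abs(wk$dx_net)), 0)
})

test_that("walks are bit-identical under the same seed", {
  sub <- uniform_substrate(40)
  sq <- seq_params(n_dummy = 4)
  fm <- field_map(sub, 45)
  w1 <- walk_spins(sub, sq, list(fm), walk_config(n_spins = 150, seed = 11))
  w2 <- walk_spins(sub, sq, list(fm), walk_config(n_spins = 150, seed = 11))
  expect_identical(w1$phase_te, w2$phase_te)
  expect_identical(w1$phase_rest, w2$phase_rest)
  expect_identical(w1$x0, w2$x0)
  # trajectory reuse: replaying twice is bit-identical
  p1 <- replay_bssfp(w1, sq)
  p2 <- replay_bssfp(w1, sq)
  expect_identical(p1$signal, p2$signal)
})

test_that("free diffusion satisfies the Einstein relation", {
  sub <- uniform_substrate(60)  # single compartment, D = 1e-9 m^2/s
  sq <- seq_params(TR = 1e-3, TE = 5e-4, n_dummy = 1)
  fm <- field_map(sub, 0, delta_chi = 0)
  wk <- walk_spins(sub, sq, list(fm), walk_config(n_spins = 10000, seed = 5))
  t_total <- 2 * sq$TR
  msd <- mean((wk$dx_net * 1e-6)^2)   # per-axis, m^2
  se <- stats::sd((wk$dx_net * 1e-6)^2) / sqrt(length(wk$dx_net))
  expect_lt(abs(msd - 2 * 1e-9 * t_total), 3 * se)
})

test_that("null-field ensembles reproduce the single-pool analytic profile", {
  # engine-equivalence control: a long dummy train isolates the engine from
  # the physical approach-to-steady-state transient
  tis <- wm_compartments("3T"); tis$T1 <- 1; tis$T2 <- 0.06; tis$pd <- 1
  sub <- uniform_substrate(40, tissues = tis)
  sq <- seq_params(n_dummy = 1536)
  f0 <- 40
  fm <- field_map(sub, 0, delta_chi = 0)
  fm$offset <- matrix(f0 / (42.577e6 * 2.89), 40, 40)
  wk <- walk_spins(sub, sq, list(fm), walk_config(n_spins = 100, seed = 3))
  prof <- dplyr::filter(replay_bssfp(wk, sq, B0 = 2.89), compartment == "all")
  an <- simulate_profile(tissue_table(T1 = 1, T2 = 0.06, freq_offset = f0), sq)
  expect_lt(max(Mod(prof$signal - 100 * an$signal)) /
              max(Mod(100 * an$signal)), 1e-3)
  # and MIRACLE recovers the input T2 (flat orientation dependence)
  fit <- fit_miracle(configuration_modes(prof), sq)
  expect_lt(abs(fit$T2 - 0.06) / 0.06, 0.02)
})

test_that("zero susceptibility gives a flat orientation dependence", {
  tis <- wm_compartments("3T")
  sub <- wm_substrate()
  sub$delta_chi <- 0
  sub$tissues <- tis
  sq <- seq_params(n_dummy = 256)
  fms <- field_map_stack(sub, c(0, 90))
  wk <- walk_spins(sub, sq, fms, walk_config(n_spins = 300, seed = 9))
  sweep <- relaxometry_from_profiles(replay_bssfp(wk, sq, B0 = 2.89), sq)
  all_r2 <- sweep$R2[sweep$compartment == "all"]
  expect_lt(diff(range(all_r2)) / mean(all_r2), 0.02)
})

test_that("R2 rises towards perpendicular fibers and myelin is most anisotropic", {
  sw <- mc_3t()$sweep
  r2 <- function(comp, th) sw$R2[sw$compartment == comp & sw$theta == th]
  expect_gt(r2("all", 90), r2("all", 0))
  aniso <- vapply(c("extra-axonal", "intra-axonal", "myelin"),
                  function(cp) rate_aniso(sw, cp), numeric(1))
  expect_gt(aniso[["myelin"]], aniso[["extra-axonal"]])
  expect_gt(aniso[["myelin"]], aniso[["intra-axonal"]])
})

test_that("R2 anisotropy is stronger at 9.4T than at 3T", {
  expect_gt(rate_aniso(mc_94t()), rate_aniso(mc_3t()$sweep))
})

test_that("doubling the susceptibility shift strengthens the R2 anisotropy", {
  m <- mc_3t()
  d1 <- with(m$sweep, R2[compartment == "all" & theta == 90] -
                      R2[compartment == "all" & theta == 0])
  d2 <- with(m$sweep_dchi2, R2[compartment == "all" & theta == 90] -
                            R2[compartment == "all" & theta == 0])
  expect_gt(d2, d1)
})

test_that("halving the time step changes R2(90) by less than 2%", {
  sub <- wm_substrate()
  preset <- spinwalk_preset("3T default")
  sub$tissues <- preset$tissues
  fm <- field_map_stack(sub, 90)
  cfg_fine <- walk_config(n_spins = 400, thetas = 90, seed = 13)
  wk1 <- walk_spins(sub, preset$seq, fm,
                    walk_config(n_spins = 400, thetas = 90, seed = 13))
  cfg_fine$dt <- 5e-6
  wk2 <- walk_spins(sub, preset$seq, fm, cfg_fine)
  r2 <- vapply(list(wk1, wk2), function(w) {
    sweep <- relaxometry_from_profiles(
      replay_bssfp(w, preset$seq, B0 = 2.89), preset$seq)
    sweep$R2[sweep$compartment == "all"]
  }, numeric(1))
  expect_lt(abs(r2[2] - r2[1]) / r2[1], 0.02)
})

test_that("timing mismatches and bad configs are rejected", {
  expect_error(walk_config(n_spins = 10), "at least 100")
  sub <- uniform_substrate(30)
  sq <- seq_params(n_dummy = 2)
  wk <- walk_spins(sub, sq, list(field_map(sub, 0, delta_chi = 0)),
                   walk_config(n_spins = 100, seed = 1))
  expect_error(replay_bssfp(wk, seq_params(TR = 10e-3, TE = 5e-3, n_dummy = 2)),
               "TR/TE")
})
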