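test_that("fiber-to-field angle folds into [0, 90] with the right landmarks", {
  expect_equal(fiber_to_field_angle(0, 0, 1), 0)
  expect_equal(fiber_to_field_angle(1, 0, 0), 90)
  expect_equal(fiber_to_field_angle(0, 1, 0), 90)
  expect_equal(fiber_to_field_angle(1, 0, 1), 45)
  expect_equal(fiber_to_field_angle(0, 0, -1), 0)   # antipodal fold
  expect_error(fiber_to_field_angle(0, 0, 0), "zero")
  set.seed(4)
  v <- matrix(rnorm(3e4), ncol = 3)
  th <- fiber_to_field_angle(v[, 1], v[, 2], v[, 3])
  expect_true(all(th >= 0 & th <= 90))
})

test_that("FA, AD, RD follow the tensor eigenvalue formulas", {
  expect_equal(fa_from_eigenvalues(1e-3, 1e-3, 1e-3)$FA, 0)
  expect_equal(fa_from_eigenvalues(1e-3, 0, 0)$FA, 1)
  x <- fa_from_eigenvalues(1.7e-3, 0.3e-3, 0.3e-3)
  expect_equal(x$FA, 0.7990, tolerance = 1e-4)
  expect_equal(x$RD / x$AD, 0.17647, tolerance = 1e-4)
  set.seed(5)
  l <- matrix(sort(runif(3)) |> rev(), 1)  # any valid triple stays in [0, 1]
  for (i in 1:200) {
    ll <- sort(runif(3, 0, 3e-3), decreasing = TRUE)
    fa <- fa_from_eigenvalues(ll[1], ll[2], ll[3])$FA
    expect_true(fa >= 0 && fa <= 1 + 1e-12)
  }
  expect_error(fa_from_eigenvalues(0, 0, 0), "zero")
})

test_that("offset angle is arctan(RD/AD) in degrees", {
  expect_equal(epsilon0_angle(1e-3, 0), 0)
  expect_equal(epsilon0_angle(1e-3, 1e-3), 45)
  expect_equal(epsilon0_angle(1.7e-3, 0.3e-3), atan(0.17647) * 180 / pi,
               tolerance = 1e-4)
  expect_equal(round(epsilon0_angle(1, 0.17647), 2), 10.01)
  expect_error(epsilon0_angle(0, 1e-3), "positive")
})

test_that("binning strategies place voxels in the documented cells", {
  vox <- tibble::tibble(FA = 0.55, theta = 37, R2 = 21)
  b <- bin_parameter(vox, "R2", strategy = 1)
  hit <- b[b$n == 1, ]
  expect_equal(c(hit$fa_lo, hit$fa_hi), c(0.4, 0.6))
  expect_equal(c(hit$ang_lo, hit$ang_hi), c(30, 37.5))
  # strategy grids
  b2 <- bin_parameter(vox, "R2", strategy = 2)
  expect_equal(nrow(b2), 36)                   # 1 FA stratum x 36 theta bins
  expect_equal(unique(b2$fa_lo), 0.5)
  b3 <- bin_parameter(vox, "R2", strategy = 3)
  expect_equal(sort(unique(b3$ang_lo)), seq(15, 85, by = 5))
  expect_equal(sort(unique(b3$fa_lo)), seq(0, 0.75, by = 0.05))
})

test_that("binning conserves counts and reduces constants exactly", {
  set.seed(8)
  vox <- tibble::tibble(FA = runif(4000), theta = runif(4000, 0, 90),
                        R2 = 20)
  b <- bin_parameter(vox, "R2", strategy = 1)
  expect_equal(sum(b$n), 4000L)
  expect_true(all(b$mean[b$n > 0] == 20))
  expect_true(all(b$sd[b$n > 1] == 0))
  # epsilon binning subtracts the voxel offset angle first (clamped at 0)
  vox$epsilon0 <- 10
  be <- bin_parameter(vox, "R2", strategy = 2, angle = "epsilon")
  eps <- pmax(0, vox$theta - 10)
  expect_equal(sum(be$n), sum(vox$FA > 0.5 | vox$FA == 0.5))
  expect_equal(max(be$ang_lo[be$n > 0]), 77.5)  # eps <= 80 populates up to that bin
})

test_that("angle edge cases go to the upper bin and the last bin is closed", {
  vox <- tibble::tibble(FA = c(0.6, 0.6, 1.0), theta = c(30, 90, 45), R2 = 1)
  b <- bin_parameter(vox, "R2", strategy = 1)
  expect_equal(b$n[abs(b$ang_lo - 30) < 1e-9 & abs(b$fa_lo - 0.6) < 1e-9][1], 1L)  # 30 -> [30, 37.5)
  expect_equal(b$n[abs(b$ang_lo - 82.5) < 1e-9 & abs(b$fa_lo - 0.6) < 1e-9][1], 1L)  # 90 closes the last bin
  expect_equal(sum(b$n[abs(b$fa_lo - 0.8) < 1e-9]), 1L)       # FA = 1 closes the last stratum
})

test_that("anisotropy percentages follow the max/min formulas", {
  expect_equal(anisotropy_percent(tibble::tibble(mean = c(22, 18), n = 1)), 10)
  expect_equal(anisotropy_percent(tibble::tibble(mean = c(0.3, 0.1), n = 1),
                                  kind = "ai"), 20)
  const <- tibble::tibble(mean = rep(5, 4), n = 1)
  expect_equal(anisotropy_percent(const), 0)
  # rate form is invariant to positive scaling; AI form is not
  cv <- tibble::tibble(mean = c(10, 14, 12), n = 1)
  cv2 <- dplyr::mutate(cv, mean = mean * 3)
  expect_equal(anisotropy_percent(cv2), anisotropy_percent(cv))
  expect_equal(anisotropy_percent(cv2, kind = "ai"),
               3 * anisotropy_percent(cv, kind = "ai"))
  # empty bins are excluded
  cv3 <- tibble::tibble(mean = c(10, 99, 14), n = c(5, 0, 5))
  expect_equal(anisotropy_percent(cv3), 100 * 4 / 24)
  expect_error(anisotropy_percent(tibble::tibble(mean = 1, n = 1)), "two")
})

test_that("the endpoint anisotropy of the fitted 3T R2 curve is about 7.2%", {
  # noiseless susceptibility-model curve with the fitted large-cohort
  # coefficients: min at 0 deg (20.04), max at 90 deg (23.14)
  y <- model_eval("susceptibility", c(a = 20.04, b = 0.03, c = 3.07), c(0, 90))
  expect_equal(100 * (y[2] - y[1]) / (y[2] + y[1]), 7.18, tolerance = 1e-3)
})

test_that("orientation_maps assembles the voxel table", {
  d <- tibble::tibble(l1 = 1.7e-3, l2 = 0.3e-3, l3 = 0.3e-3,
                      v1x = 1, v1y = 0, v1z = 1)
  om <- orientation_maps(d)
  expect_equal(om$theta, 45)
  expect_equal(om$FA, 0.7990, tolerance = 1e-4)
  expect_equal(om$epsilon0, epsilon0_angle(1.7e-3, 0.3e-3))
})
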