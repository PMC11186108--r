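test_that("calibration factor estimation is exact, inverse-linear and noise-robust", {
  g <- grid_centered(c(16, 16, 16), rep(4.42, 3))
  truth_vals <- array(runif(prod(g$shape), 10, 100), g$shape)
  truth <- activity_grid(g, truth_vals, unit = "Bq")
  ident <- activity_grid(g, truth_vals, unit = "counts")
  expect_equal(estimate_calibration_factor(ident, truth)$value, 1.0)
  half <- activity_grid(g, truth_vals / 2, unit = "counts")
  expect_equal(estimate_calibration_factor(half, truth)$value, 2.0)
  # Poisson run with ~1e6 total counts recovers 1/sensitivity within 1%
  sens <- 0.5
  set.seed(4)
  counts <- activity_grid(g, array(rpois(prod(g$shape), truth_vals * sens * 500),
                                   g$shape), unit = "counts")
  cf <- estimate_calibration_factor(counts, truth)
  expect_equal(cf$value, 1 / (sens * 500), tolerance = 0.01)
  zero <- activity_grid(g, truth_vals * 0, unit = "counts")
  expect_error(estimate_calibration_factor(zero, truth), "zero total counts")
})

test_that("counts_to_activity converts units linearly", {
  g <- grid_centered(c(6, 6, 6), rep(4, 3))
  counts <- activity_grid(g, array(10, g$shape), unit = "counts")
  cf1 <- calibration_factor(1)
  out <- counts_to_activity(counts, cf1)
  expect_equal(out$unit, "Bq")
  expect_equal(out$values, counts$values)
  out2 <- counts_to_activity(counts, calibration_factor(3.5))
  expect_equal(out2$values, 3.5 * out$values)
  zero <- activity_grid(g, array(0, g$shape), unit = "counts")
  expect_true(all(counts_to_activity(zero, cf1)$values == 0))
  expect_error(counts_to_activity(out, cf1), "not in counts")
})

test_that("background masking removes exactly the out-of-VOI activity", {
  g <- grid_centered(c(24, 24, 24), rep(4.42, 3))
  r <- sphere_radius_from_volume(16)
  frac <- sphere_voi_weights(g, c(0, 0, 0), r, subsamples = 3L)
  act <- activity_grid(g, frac * 1e4, unit = "Bq")
  whole <- mask_background(act, array(1, g$shape))
  expect_equal(whole$values, act$values)
  expect_equal(attr(whole, "removed_fraction"), 0)
  exact <- mask_background(act, frac)
  expect_equal(exact$values, act$values)  # nothing outside the exact VOI
  expect_error(mask_background(act, array(0, g$shape)), "empty")
})

test_that("masking a blurred image removes the spill-out complement of the RC", {
  sc <- scanner_model(spect_grid = grid_centered(c(32, 32, 32), rep(4.42, 3)),
                      noise = "none")
  r <- sphere_radius_from_volume(16)
  g <- sc$spect_grid
  fine <- grid_centered(c(60, 60, 60), rep(2.21, 3))
  frac <- sphere_voi_weights(fine, c(0, 0, 0), r, subsamples = 2L)
  truth <- activity_grid(fine, frac * 1e6 / sum(frac), unit = "Bq")
  counts <- simulate_spect(truth, sc)
  act <- counts_to_activity(counts, calibration_factor(
    1 / (sc$sensitivity_cps_per_bq * sc$scan_duration_s)))
  support <- sphere_support_mask(g, c(0, 0, 0), r)
  masked <- mask_background(act, support)
  rc <- measure_recovery_coefficient(16, sc)
  removed <- attr(masked, "removed_fraction")
  expect_equal(1 - removed, rc$value, tolerance = 0.02)
})

test_that("recovery-coefficient application rescales the VOI mean exactly", {
  rc <- recovery_coefficient(0.554, 16)
  expect_equal(apply_recovery_coefficient(12.8, rc), 23.1, tolerance = 5e-4)
  expect_equal(apply_recovery_coefficient(5, recovery_coefficient(1, 16)), 5)
  g <- grid_centered(c(12, 12, 12), rep(4.42, 3))
  r <- sphere_radius_from_volume(16)
  voi <- sphere_support_mask(g, c(0, 0, 0), r)
  act <- activity_grid(g, array(7, g$shape), unit = "Bq")
  out <- apply_rc_to_image(act, voi, rc)
  expect_equal(sum(out$values[voi]) / 16,
               apply_recovery_coefficient(sum(act$values[voi]) / 16, rc))
  expect_error(recovery_coefficient(0, 16))
  expect_error(recovery_coefficient(1.2, 16))
})

test_that("percent vs administered reproduces the printed quantification residuals", {
  rec <- administration_record(748e6, 16.87, 7.1)
  nuc <- fixture_nuclide()
  ref <- 748e6 / 16 * exp(-decay_constant(8.0197) * 7.1)
  expect_equal(percent_vs_administered(ref, rec, nuc, 16), 0)
  expect_equal(percent_vs_administered(12.8e6, rec, nuc, 16), -49.4,
               tolerance = 1e-3)
  expect_equal(percent_vs_administered(23.1e6, rec, nuc, 16), -8.7,
               tolerance = 5e-3)
})

test_that("CT-number mapping hits its anchors and round-trips densities", {
  expect_equal(hu_to_density(0), 1.000)
  expect_equal(hu_to_density(-1000), 0.001)
  expect_warning(hu_to_density(-1200), "clamped")
  for (d in c(1.0, 1.19)) {
    expect_equal(hu_to_density(rptdose:::density_to_hu(d)), d,
                 tolerance = 0.002)
  }
  g <- grid_centered(c(4, 4, 4), rep(1, 3))
  dens <- array(c(0.0012, 1.0, 1.19, 0.9), c(4, 4, 4))
  mg <- density_to_material(dens, g)
  expect_equal(mg$codes[1, 1, 1], 1L)  # air
  expect_equal(mg$codes[2, 1, 1], 2L)  # water
  expect_equal(mg$codes[3, 1, 1], 3L)  # acrylic
  expect_equal(mg$codes[4, 1, 1], 2L)  # water-like
})

test_that("resampling preserves identity, constants and reports change", {
  g <- grid_centered(c(12, 12, 12), rep(4.42, 3))
  vals <- array(runif(prod(g$shape)), g$shape)
  act <- activity_grid(g, vals, unit = "Bq")
  same <- resample_to_grid(act, g)
  expect_equal(same$values, vals, tolerance = 1e-12)
  expect_equal(attr(same, "total_change"), 0, tolerance = 1e-12)
  # a uniform concentration stays uniform on any overlapping grid
  uni <- activity_grid(g, array(voxel_volume_ml(g) * 3, g$shape), unit = "Bq")
  g2 <- grid_centered(c(20, 20, 6), c(2.1, 2.1, 6.5))
  out <- resample_to_grid(uni, g2)
  conc <- out$values / voxel_volume_ml(g2)
  expect_true(all(abs(conc - 3) < 1e-9))
})
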