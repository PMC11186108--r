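small_truth <- function(total_bq = 1e6) {
  g <- grid_centered(c(24, 24, 24), rep(4.42, 3))
  r <- sphere_radius_from_volume(16)
  frac <- sphere_voi_weights(g, c(0, 0, 0), r, subsamples = 3L)
  activity_grid(g, frac * total_bq / sum(frac), unit = "Bq")
}

small_scanner <- function(...) {
  scanner_model(spect_grid = grid_centered(c(24, 24, 24), rep(4.42, 3)), ...)
}

test_that("with no blur, no noise and unit scale, counts equal the truth", {
  sc <- small_scanner(psf_fwhm_mm = 0, sensitivity_cps_per_bq = 1,
                      scan_duration_s = 1, noise = "none")
  tr <- small_truth()
  out <- simulate_spect(tr, sc)
  expect_equal(out$unit, "counts")
  expect_equal(out$values, tr$values, tolerance = 1e-12)
})

test_that("zero activity yields zero counts and blur conserves counts", {
  sc <- small_scanner(noise = "none")
  tr <- small_truth()
  zero <- activity_grid(tr$grid, tr$values * 0, unit = "Bq")
  expect_true(all(simulate_spect(zero, sc)$values == 0))
  out <- simulate_spect(tr, sc)
  expected_total <- sum(tr$values) * sc$sensitivity_cps_per_bq * sc$scan_duration_s
  expect_equal(sum(out$values), expected_total, tolerance = 5e-3)
  # blur strictly lowers the peak
  sharp <- simulate_spect(tr, small_scanner(psf_fwhm_mm = 0, noise = "none"))
  expect_lt(max(out$values), max(sharp$values))
})

test_that("seeded acquisitions are bit-identical and unbiased", {
  sc <- small_scanner(seed = 99)
  tr <- small_truth(total_bq = 1e7)
  a <- simulate_spect(tr, sc)
  b <- simulate_spect(tr, sc)
  expect_identical(a$values, b$values)
  # mean of seeded replicates matches the noise-free image within 3 SE
  noiseless <- simulate_spect(tr, small_scanner(noise = "none"))$values
  reps <- vapply(1:50, function(s)
    as.numeric(simulate_spect(tr, small_scanner(seed = s))$values),
    numeric(length(noiseless)))
  pick <- which(noiseless > quantile(noiseless, 0.95))[1:100]
  pick <- pick[!is.na(pick)]
  m <- rowMeans(reps[pick, , drop = FALSE])
  se <- sqrt(noiseless[pick] / 50)
  expect_true(all(abs(m - noiseless[pick]) <= 3 * se + 1e-9))
})

test_that("CT simulation maps materials onto the density scale", {
  g <- grid_centered(c(10, 10, 10), rep(4, 3))
  codes <- array(2L, g$shape)
  codes[1, 1, 1] <- 1L  # air corner
  mg <- material_grid(g, codes)
  sc <- scanner_model(ct_grid = g, noise = "none")
  ct <- simulate_ct(mg, sc)
  expect_equal(ct$values[5, 5, 5], 0, tolerance = 1e-9)       # water anchor
  expect_lt(ct$values[1, 1, 1], -900)                          # air corner
  acr <- material_grid(g, array(3L, g$shape))
  ct2 <- simulate_ct(acr, sc)
  expect_gt(ct2$values[5, 5, 5], 0)                            # acrylic positive
  expect_equal(hu_to_density(ct2$values[5, 5, 5]), 1.19, tolerance = 0.01)
})

test_that("calibration scan is linear and flat in the deep interior", {
  sc <- scanner_model(noise = "none",
                      spect_grid = grid_centered(c(64, 64, 48), rep(4.42, 3)))
  cal <- calibration_scan(5.64, 1e3, sc, radius_mm = 108)
  vox_act <- 1e3 * voxel_volume_ml(sc$spect_grid)
  expected <- vox_act * sc$sensitivity_cps_per_bq * sc$scan_duration_s
  ctr <- (sc$spect_grid$shape + 1) / 2
  deep <- cal$counts$values[(ctr[1] - 3):(ctr[1] + 3),
                            (ctr[2] - 3):(ctr[2] + 3),
                            (ctr[3] - 1):(ctr[3] + 1)]
  expect_true(all(abs(deep - expected) / expected < 1e-3))
  cal2 <- calibration_scan(5.64, 2e3, sc, radius_mm = 108)
  expect_equal(cal2$counts$values, 2 * cal$counts$values, tolerance = 1e-9)
})

test_that("recovery coefficients have the correct limits and ordering", {
  rc0 <- measure_recovery_coefficient(16, small_scanner(psf_fwhm_mm = 0,
                                                        noise = "none"))
  expect_equal(rc0$value, 1.0, tolerance = 1e-9)
  rcs <- vapply(c(4, 8, 12, 16), function(f)
    measure_recovery_coefficient(16, small_scanner(psf_fwhm_mm = f,
                                                   noise = "none"))$value,
    numeric(1))
  expect_true(all(diff(rcs) < 0))
  rc2 <- measure_recovery_coefficient(2, small_scanner(noise = "none"))
  rc16 <- measure_recovery_coefficient(16, small_scanner(noise = "none"))
  expect_gt(rc16$value, rc2$value)
})
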