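test_that("linear calibration recovers exact and noisy dose-response", {
  doses <- rep(c(0.25, 0.5, 1, 2, 4), each = 4)
  signals <- doses / 0.01
  fit <- fit_calibration(signals, doses)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  fit2 <- fit_calibration(signals * 2, doses)
  expect_equal(fit2$slope, 0.005, tolerance = 1e-12)
  set.seed(8)
  noisy <- signals * (1 + rnorm(length(signals), 0, 0.03))
  fit3 <- fit_calibration(noisy, doses)
  expect_equal(fit3$slope, 0.01, tolerance = 0.02)
  expect_error(fit_calibration(rep(5, 4), doses[1:4]), "degenerate")
})

test_that("energy correction interpolates log-linearly between anchors", {
  curve <- default_response_curve()
  expect_equal(energy_correction(111, curve, 111), 1.0)
  flat <- energy_response_curve(c(50, 700), c(1, 1))
  expect_equal(energy_correction(237, flat, 111), 1.0)
  # hand-computed: log-midpoint of two anchors gives the mean response
  two <- energy_response_curve(c(111, 662), c(1.3, 1.0))
  emid <- exp(mean(log(c(111, 662))))
  expect_equal(energy_correction(emid, two, 111),
               1.3 / mean(c(1.3, 1.0)), tolerance = 1e-12)
  expect_error(energy_correction(-5, curve), "positive")
  expect_warning(energy_correction(5, curve), "extrapolating")
})

test_that("the 6% rule flags only readings deviating beyond six percent of the mean", {
  calib <- list(slope = 1, intercept = 0)
  g1 <- flag_outliers(tld_group(1, c(1.00, 1.00, 1.00, 1.05), calib, 200))
  expect_false(any(g1$outlier_flags))  # max deviation 3.7%
  g2 <- flag_outliers(tld_group(2, c(1.00, 1.00, 1.00, 1.10), calib, 200))
  expect_identical(g2$outlier_flags, c(FALSE, FALSE, FALSE, TRUE))  # 7.3%
  g3 <- flag_outliers(tld_group(3, rep(2.2, 4), calib, 200))
  expect_false(any(g3$outlier_flags))
})

test_that("probe reduction reports mean and scale-invariant sd percent", {
  calib <- list(slope = 1, intercept = 0)
  curve <- energy_response_curve(c(50, 700), c(1, 1))
  g <- correct_tld_group(tld_group(1, rep(2.37, 4), calib, 200), curve)
  red <- reduce_probe(g)
  expect_equal(red$dose_gy, 2.37)
  expect_equal(red$sd_pct, 0)
  g2 <- correct_tld_group(tld_group(2, c(1, 1.02, 0.98, 1.01), calib, 200),
                          curve)
  r2 <- reduce_probe(g2)
  g3 <- correct_tld_group(tld_group(3, 7 * c(1, 1.02, 0.98, 1.01), calib, 200),
                          curve)
  r3 <- reduce_probe(g3)
  expect_equal(r3$dose_gy, 7 * r2$dose_gy)
  expect_equal(r3$sd_pct, r2$sd_pct)
  # known 3% population sd is recovered on average across seeds
  set.seed(15)
  sds <- replicate(400, {
    reduce_probe(correct_tld_group(
      tld_group(1, 2 * (1 + rnorm(4, 0, 0.03)), calib, 200), curve))$sd_pct
  })
  expect_equal(mean(sds), 3, tolerance = 0.12)
})

test_that("calibration slope and energy factor commute", {
  curve <- default_response_curve()
  calib <- list(slope = 0.01, intercept = 0)
  readings <- c(100, 102, 98, 101)
  g <- correct_tld_group(tld_group(1, readings, calib, 240), curve)
  f <- energy_correction(240, curve, 111)
  expect_equal(g$corrected_doses_gy, (readings * 0.01) * f)
  expect_equal(g$corrected_doses_gy, (readings * f) * 0.01)
})

test_that("measurement-model closure: simulated readings reduce to the true dose", {
  curve <- default_response_curve()
  true_dose <- 2.06
  for (e_kev in c(150, 200, 280)) {
    set.seed(44)
    readings <- simulate_tld_readings(true_dose, n_chips = 4,
                                      slope_gy_per_signal = 0.01,
                                      curve = curve, mean_energy_kev = e_kev,
                                      repeatability_pct = 0)
    g <- tld_group(1, readings, list(slope = 0.01, intercept = 0), e_kev)
    g <- correct_tld_group(g, curve)
    expect_equal(reduce_probe(g)$dose_gy, true_dose, tolerance = 1e-12)
  }
})

test_that("quadrature budget combination and the conservative override", {
  b1 <- combine_uncertainty(c(5), k = 2)
  expect_equal(b1$combined_percent, 10)
  b2 <- combine_uncertainty(c(4.4, 0.6, 2.0, 4.0), k = 1)
  expect_equal(b2$combined_percent, 6.3, tolerance = 5e-3)
  b3 <- combine_uncertainty(c(4.4, 0.6, 2.0, 4.0), k = 2,
                            conservative_override = 10)
  expect_equal(b3$combined_percent, 12.6, tolerance = 5e-3)
  expect_equal(b3$adopted_percent, 10)
  expect_equal(combine_uncertainty(numeric(0), k = 2)$combined_percent, 0)
  expect_error(combine_uncertainty(c(1), k = 0), "positive")
  # monotone: adding a component never decreases the combination
  base <- combine_uncertainty(c(3, 4), k = 1)$combined_percent
  for (extra in c(0, 0.5, 2, 6)) {
    expect_gte(combine_uncertainty(c(3, 4, extra), k = 1)$combined_percent,
               base)
  }
})
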