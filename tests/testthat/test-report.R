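fake_dose <- function(values, grid, rel = 0) {
  structure(list(grid = grid, dose = values,
                 rel_uncertainty = array(rel, grid$shape),
                 histories = 1, unit = "Gy", n_batches = 2,
                 spectra = NULL,
                 energy_balance = list(emitted_kev = 0, deposited_kev = 0,
                                       escaped_kev = 0)),
            class = "dose_grid")
}

test_that("ROI mean dose handles uniform fields, single voxels and gradients", {
  g <- grid_centered(c(21, 21, 21), rep(2, 3))
  uni <- fake_dose(array(4.2, g$shape), g)
  expect_equal(roi_mean_dose(uni, c(3, -5, 7), edge_mm = 6)$dose, 4.2)
  expect_equal(roi_mean_dose(uni, c(0, 0, 0), edge_mm = 13)$dose, 4.2)
  one <- roi_mean_dose(uni, c(0, 0, 0), edge_mm = 2)
  expect_equal(one$dose, 4.2)
  # linear gradient: ROI mean equals the field at the ROI centroid
  cx <- axis_coords(g, 1)
  grad <- fake_dose(array(rep(2 + 0.3 * cx, times = 21 * 21), g$shape), g)
  roi <- roi_mean_dose(grad, c(5, 0, 0), edge_mm = 7, subsamples = 4L)
  expect_equal(roi$dose, 2 + 0.3 * 5, tolerance = 1e-3)
  expect_error(roi_mean_dose(uni, c(1000, 0, 0)), "overlap")
})

test_that("percent differences use the measurement as reference", {
  expect_equal(percent_difference(2.37, 2.37), 0)
  expect_equal(percent_difference(2.06, 2.17), -5.34, tolerance = 1e-3)
  expect_equal(percent_difference(1, 0.9), 10)
  expect_error(percent_difference(0, 1), "positive")
})

make_measured <- function(doses, sd_pct = 2) {
  lapply(seq_along(doses), function(k)
    list(probe_id = k, dose_gy = doses[k], sd_pct = sd_pct, n = 4,
         n_outliers = 0))
}
make_mode <- function(doses, rel = 0.01) {
  lapply(doses, function(d) list(dose = d, rel_uncertainty = rel,
                                 n_voxels = 25))
}

test_that("identical modes agree perfectly and the verdict keys on the budget", {
  budget <- combine_uncertainty(c(4.4, 0.6, 2.0, 4.0), k = 2,
                                conservative_override = 10)
  doses <- c(2.37, 0.98, 0.49, 0.27, 2.06, 2.49)
  tab <- agreement_report(make_measured(doses), make_mode(doses),
                          make_mode(doses), budget)
  expect_true(all(tab$within_uncertainty))
  expect_equal(attr(tab, "ranges")$image, c(0, 0))
  # one probe at +15% with a 10% budget fails alone
  img <- doses
  img[3] <- doses[3] * 0.85
  tab2 <- agreement_report(make_measured(doses), make_mode(img),
                           make_mode(doses), budget)
  expect_identical(which(!tab2$within_uncertainty), 3L)
  expect_equal(tab2$pct_diff_image[3], 15, tolerance = 1e-12)
})

test_that("missing probes are incomplete, not fatal, and reports are pure functions", {
  budget <- combine_uncertainty(c(5), k = 2)
  doses <- c(1, 2, 3)
  tab <- agreement_report(make_measured(doses), make_mode(doses)[1:2],
                          make_mode(doses), budget)
  expect_false(tab$complete[3])
  expect_true(is.na(tab$pct_diff_image[3]))
  tab_b <- agreement_report(make_measured(doses), make_mode(doses)[1:2],
                            make_mode(doses), budget)
  expect_identical(as.data.frame(tab), as.data.frame(tab_b))
})

test_that("report files are written and consistent with the table", {
  budget <- combine_uncertainty(c(5), k = 2)
  doses <- c(1.5, 0.75)
  tab <- agreement_report(make_measured(doses), make_mode(doses * 1.02),
                          make_mode(doses), budget)
  dir <- withr::local_tempdir()
  paths <- write_agreement_report(tab, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths["csv"])
  expect_equal(back$measured_gy, doses)
  js <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(js$table$pct_diff_image, tab$pct_diff_image, tolerance = 1e-12)
})
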