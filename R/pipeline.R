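#' Build a pipeline run configuration
#'
#' Aggregates every knob of the end-to-end validation run with the study
#' defaults: 748 MBq of I-131 in a 16 ml sphere inside the 6.4 L cylinder,
#' a 16.87 d exposure window, a scan at 7.1 d, the 128^3 / 4.42 mm SPECT
#' grid, the 0.98 x 0.98 x 5 mm CT grid and a 247 x 253 x 52 voxel dose
#' grid at 0.977 x 0.977 x 5.0 mm. Histories are scaled to desk hardware;
#' raise them for higher-fidelity runs. Every stochastic stage derives its
#' stream from `seed`.
#'
#' @param seed master RNG seed.
#' @param a_admin_bq administered activity, Bq.
#' @param t_exposed_days TLD exposure window, days.
#' @param t_scan_days SPECT scan time post administration, days.
#' @param image_histories,ideal_histories Monte Carlo decays per mode.
#' @param n_batches uncertainty batches.
#' @param cutoff_kev photon transport cutoff.
#' @param psf_fwhm_mm scanner PSF.
#' @param sensitivity_cps_per_bq,scan_duration_s scanner sensitivity model.
#' @param phantom a `phantom_config`.
#' @param truth_spacing_mm voxel pitch of the ground-truth rasterization.
#' @param dose_grid `grid_spec` for quantified activity, materials and dose.
#' @param calibration_conc_bq_ml concentration of the 5.64 L calibration
#'   cylinder fill.
#' @param tld list of TLD-model settings (chips, slope, noise percents,
#'   calibration doses, calibration beam energy).
#' @param budget_components_pct uncertainty components at k = 1, percent.
#' @param budget_k coverage factor.
#' @param budget_override_pct adopted conservative expanded uncertainty.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       a_admin_bq = 748e6,
                       t_exposed_days = 16.87,
                       t_scan_days = 7.1,
                       image_histories = 2e7,
                       ideal_histories = 4e7,
                       n_batches = 10L,
                       cutoff_kev = 10,
                       psf_fwhm_mm = 12,
                       sensitivity_cps_per_bq = 1.4e-5,
                       scan_duration_s = 3600,
                       phantom = phantom_config(),
                       truth_spacing_mm = 2.21,
                       dose_grid = grid_centered(c(247, 253, 52),
                                                 c(0.977, 0.977, 5.0)),
                       calibration_conc_bq_ml = 1e5,
                       tld = list(n_chips = 4L, slope_gy_per_signal = 0.01,
                                  repeatability_pct = 3,
                                  calibration_noise_pct = 1.5,
                                  calibration_doses_gy = c(0.25, 0.5, 1, 2, 4),
                                  calibration_energy_kev = 111),
                       budget_components_pct = c(tld_chain = 4.4,
                                                 energy_correction = 0.6,
                                                 energy_interpolation = 2.0,
                                                 setup_modeling = 4.0),
                       budget_k = 2,
                       budget_override_pct = 10) {
  structure(list(seed = as.integer(seed), a_admin_bq = a_admin_bq,
                 t_exposed_days = t_exposed_days, t_scan_days = t_scan_days,
                 image_histories = image_histories,
                 ideal_histories = ideal_histories,
                 n_batches = as.integer(n_batches), cutoff_kev = cutoff_kev,
                 psf_fwhm_mm = psf_fwhm_mm,
                 sensitivity_cps_per_bq = sensitivity_cps_per_bq,
                 scan_duration_s = scan_duration_s,
                 phantom = phantom, truth_spacing_mm = truth_spacing_mm,
                 dose_grid = dose_grid,
                 calibration_conc_bq_ml = calibration_conc_bq_ml,
                 tld = tld,
                 budget_components_pct = budget_components_pct,
                 budget_k = budget_k,
                 budget_override_pct = budget_override_pct),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar overrides of [run_config()] defaults; nested keys `phantom` and
#' `tld` override the corresponding argument fields. Unknown keys raise an
#' error (unit-suffixed key names are part of the schema).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  simple <- setdiff(names(formals(run_config)), c("phantom", "tld", "dose_grid"))
  for (k in names(y)) {
    if (k %in% simple) {
      args[[k]] <- y[[k]]
    } else if (k == "phantom") {
      ph <- y$phantom
      if (!is.null(ph$probe_positions))
        ph$probe_positions <- do.call(rbind, lapply(ph$probe_positions,
                                                    as.numeric))
      if (!is.null(ph$sphere_center))
        ph$sphere_center <- as.numeric(ph$sphere_center)
      args$phantom <- do.call(phantom_config, ph)
    } else if (k == "tld") {
      tl <- formals(run_config)$tld
      tl <- eval(tl)
      tl[names(y$tld)] <- y$tld
      args$tld <- tl
    } else if (k == "dose_grid") {
      args$dose_grid <- grid_spec(y$dose_grid$shape, y$dose_grid$spacing,
                                  y$dose_grid$origin)
    } else {
      stop("unknown run-config key: ", k)
    }
  }
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$phantom <- list(cylinder_volume_l = config$phantom$cylinder_volume_l,
                    cylinder_radius_mm = config$phantom$cylinder_radius_mm,
                    sphere_volume_ml = config$phantom$sphere_volume_ml,
                    sphere_center = config$phantom$sphere_center,
                    probe_positions = lapply(
                      seq_len(nrow(config$phantom$probe_positions)),
                      function(i) unname(as.numeric(
                        config$phantom$probe_positions[i, ]))))
  y$dose_grid <- list(shape = config$dose_grid$shape,
                      spacing = config$dose_grid$spacing,
                      origin = config$dose_grid$origin)
  yaml::write_yaml(y, path)
  invisible(path)
}

scanner_from_config <- function(config, seed_offset = 0L) {
  scanner_model(psf_fwhm_mm = config$psf_fwhm_mm,
                sensitivity_cps_per_bq = config$sensitivity_cps_per_bq,
                scan_duration_s = config$scan_duration_s,
                noise = "poisson",
                seed = config$seed + seed_offset)
}

#' Run the full validation pipeline
#'
#' Chains every stage: phantom voxelization, synthetic SPECT/CT,
#' calibration-factor and recovery-coefficient measurements, absolute
#' quantification with background masking and partial-volume correction,
#' resampling to the dose grid, Monte Carlo dose in image and idealized
#' modes, TLD reading simulation and reduction, and the agreement report.
#' Identical configurations (same seed) reproduce every stochastic output
#' bit-identically.
#'
#' @param config a `run_config`.
#' @param out_dir optional directory: volumes, report files and a JSON
#'   manifest are written there.
#' @param verbose print stage progress.
#' @return An `rpt_validation` result object.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))

  nuclide <- i131_nuclide()
  xs <- cross_section_table()
  lambda <- decay_constant(nuclide$half_life_days)
  record <- administration_record(config$a_admin_bq, config$t_exposed_days,
                                  config$t_scan_days)
  phantom <- build_phantom(config$phantom)
  scanner <- scanner_from_config(config)

  # --- ground truth rasterization at scan-time activity
  t1 <- tic()
  ext <- c(2 * phantom$cylinder$r + 24, 2 * phantom$cylinder$r + 24,
           phantom$cylinder$h + 24)
  truth_grid <- grid_centered(ceiling(ext / config$truth_spacing_mm),
                              rep(config$truth_spacing_mm, 3))
  a_scan <- activity_at(record, lambda, config$t_scan_days)
  vox <- voxelize(phantom, truth_grid, total_bq = a_scan, subsamples = 2L)
  timings["voxelize"] <- tic() - t1
  say("voxelized phantom (%.1f s)", timings["voxelize"])

  # --- synthetic acquisition
  t1 <- tic()
  counts <- simulate_spect(vox$activity, scanner)
  ct <- simulate_ct(vox$materials, scanner)
  timings["acquisition"] <- tic() - t1
  say("synthesized SPECT/CT (%.1f s)", timings["acquisition"])

  # --- calibration chain (separate scans: independent noise streams)
  t1 <- tic()
  cal <- calibration_scan(5.64, config$calibration_conc_bq_ml,
                          scanner_from_config(config, 101L))
  cf <- estimate_calibration_factor(cal$counts, cal$truth)
  rc <- measure_recovery_coefficient(config$phantom$sphere_volume_ml,
                                     scanner, cf = cf)
  timings["calibration"] <- tic() - t1
  say("CF = %.4g Bq/count, RC = %.3f (%.1f s)", cf$value, rc$value,
      timings["calibration"])

  # --- quantification
  t1 <- tic()
  act <- counts_to_activity(counts, cf)
  voi_spect <- sphere_support_mask(scanner$spect_grid, phantom$sphere$center,
                                   phantom$sphere$r)
  masked <- mask_background(act, voi_spect)
  v_ml <- config$phantom$sphere_volume_ml
  apparent <- apparent_mean_conc(masked$values, voi_spect, v_ml)
  pct_no_pvc <- percent_vs_administered(apparent, record, nuclide, v_ml)
  corrected_conc <- apply_recovery_coefficient(apparent, rc)
  pct_pvc <- percent_vs_administered(corrected_conc, record, nuclide, v_ml)
  img_corr <- apply_rc_to_image(masked, voi_spect, rc)
  act_dose_grid <- resample_to_grid(img_corr, config$dose_grid)
  voi_dose <- sphere_support_mask(config$dose_grid, phantom$sphere$center,
                                  phantom$sphere$r)
  resample_change_pct <- 100 *
    (apparent_mean_conc(act_dose_grid$values, voi_dose, v_ml) /
       apparent_mean_conc(img_corr$values, voi_spect, v_ml) - 1)
  timings["quantification"] <- tic() - t1
  say("quantified: %.2f MBq/ml raw (%.1f%%), %.2f MBq/ml corrected (%.1f%%)",
      apparent / 1e6, pct_no_pvc, corrected_conc / 1e6, pct_pvc)

  # --- materials for dose computation
  t1 <- tic()
  density_ct <- hu_to_density(ct$values)
  density_dose <- resample_trilinear(density_ct, ct$grid, config$dose_grid,
                                     fill = 0.001)
  mat_image <- density_to_material(density_dose, config$dose_grid)
  mat_ideal <- voxelize(phantom, config$dose_grid, total_bq = 0,
                        subsamples = 1L)$materials
  timings["materials"] <- tic() - t1

  # --- cumulated activities
  a_tilde_ideal <- integrated_activity(record, lambda)
  a_img_t0 <- sum(act_dose_grid$values) * exp(lambda * config$t_scan_days)
  a_tilde_image <- integrated_activity(
    administration_record(a_img_t0, config$t_exposed_days,
                          config$t_scan_days), lambda)

  # --- Monte Carlo dose, both modes
  scorers <- scorer_spec(config$phantom$probe_positions, edge_mm = 5)
  t1 <- tic()
  dose_image <- run_dose(act_dose_grid, mat_image, nuclide, xs,
                         scorers = scorers,
                         histories = config$image_histories,
                         seed = config$seed + 303L,
                         n_batches = config$n_batches,
                         cutoff_kev = config$cutoff_kev)
  timings["dose_image"] <- tic() - t1
  say("image-mode transport done (%.1f s)", timings["dose_image"])
  t1 <- tic()
  dose_ideal <- run_dose(list(center = phantom$sphere$center,
                              radius_mm = phantom$sphere$r),
                         mat_ideal, nuclide, xs, scorers = scorers,
                         histories = config$ideal_histories,
                         seed = config$seed + 404L,
                         n_batches = config$n_batches,
                         cutoff_kev = config$cutoff_kev)
  timings["dose_ideal"] <- tic() - t1
  say("idealized transport done (%.1f s)", timings["dose_ideal"])

  abs_image <- absolute_dose_map(dose_image, a_tilde_image)
  abs_ideal <- absolute_dose_map(dose_ideal, a_tilde_ideal)

  # probe doses from the track-length scorer estimator (low variance in
  # the 5 mm cubes; uncertainty from independent-batch spread)
  probes <- config$phantom$probe_positions
  roi_image <- lapply(seq_len(nrow(probes)), function(k)
    list(dose = abs_image$scorer_dose$dose[k],
         rel_uncertainty = abs_image$scorer_dose$rel_uncertainty[k],
         n_voxels = NA_integer_))
  roi_ideal <- lapply(seq_len(nrow(probes)), function(k)
    list(dose = abs_ideal$scorer_dose$dose[k],
         rel_uncertainty = abs_ideal$scorer_dose$rel_uncertainty[k],
         n_voxels = NA_integer_))
  mean_energies <- vapply(dose_ideal$spectra, mean_energy, numeric(1))

  # --- TLD measurement model
  t1 <- tic()
  curve <- default_response_curve()
  tldc <- config$tld
  measured <- with_seed(config$seed + 202L, function() {
    cal_doses <- rep(tldc$calibration_doses_gy, each = tldc$n_chips)
    cal_signals <- cal_doses / tldc$slope_gy_per_signal *
      (1 + stats::rnorm(length(cal_doses), 0, tldc$calibration_noise_pct / 100))
    calib <- fit_calibration(cal_signals, cal_doses)
    lapply(seq_len(nrow(probes)), function(k) {
      readings <- simulate_tld_readings(
        roi_ideal[[k]]$dose, n_chips = tldc$n_chips,
        slope_gy_per_signal = tldc$slope_gy_per_signal, curve = curve,
        mean_energy_kev = mean_energies[k],
        calibration_energy_kev = tldc$calibration_energy_kev,
        repeatability_pct = tldc$repeatability_pct)
      g <- tld_group(k, readings, calib, mean_energies[k])
      g <- correct_tld_group(g, curve, tldc$calibration_energy_kev)
      g <- flag_outliers(g)
      reduce_probe(g)
    })
  })
  timings["tld"] <- tic() - t1

  budget <- combine_uncertainty(config$budget_components_pct,
                                k = config$budget_k,
                                conservative_override = config$budget_override_pct)
  table <- agreement_report(measured, roi_image, roi_ideal, budget)
  timings["total"] <- tic() - t0

  result <- structure(list(
    config = config, phantom = phantom,
    cf = cf, rc = rc,
    apparent_conc_bq_ml = apparent, corrected_conc_bq_ml = corrected_conc,
    pct_vs_admin_no_pvc = pct_no_pvc, pct_vs_admin_pvc = pct_pvc,
    resample_change_pct = resample_change_pct,
    a_tilde_ideal = a_tilde_ideal, a_tilde_image = a_tilde_image,
    dose_image = abs_image, dose_ideal = abs_ideal,
    roi_image = roi_image, roi_ideal = roi_ideal,
    mean_energies_kev = mean_energies,
    measured = measured, budget = budget, table = table,
    timings = timings), class = "rpt_validation")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(counts$values, counts$grid, file.path(out_dir, "spect_counts.nii.gz"))
    write_volume(ct$values, ct$grid, file.path(out_dir, "ct.nii.gz"))
    write_volume(abs_image$dose, abs_image$grid, file.path(out_dir, "dose_image.nii.gz"))
    write_volume(abs_ideal$dose, abs_ideal$grid, file.path(out_dir, "dose_ideal.nii.gz"))
    write_agreement_report(table, out_dir)
    jsonlite::write_json(pipeline_manifest(result),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

# machine-readable summary of every reported number (reproducible from the
# same config: pure function of the result)
pipeline_manifest <- function(result) {
  tab <- as.data.frame(result$table)
  list(seed = result$config$seed,
       histories = list(image = result$config$image_histories,
                        ideal = result$config$ideal_histories),
       calibration_factor_bq_per_count = result$cf$value,
       recovery_coefficient = result$rc$value,
       apparent_conc_bq_ml = result$apparent_conc_bq_ml,
       corrected_conc_bq_ml = result$corrected_conc_bq_ml,
       pct_vs_admin_no_pvc = result$pct_vs_admin_no_pvc,
       pct_vs_admin_pvc = result$pct_vs_admin_pvc,
       resample_change_pct = result$resample_change_pct,
       a_tilde_ideal_bq_s = result$a_tilde_ideal$a_tilde_bq_s,
       a_tilde_image_bq_s = result$a_tilde_image$a_tilde_bq_s,
       mean_energies_kev = result$mean_energies_kev,
       budget = list(combined_percent = result$budget$combined_percent,
                     adopted_percent = result$budget$adopted_percent,
                     k = result$budget$k),
       table = tab,
       timings_s = as.list(result$timings))
}

#' @export
print.rpt_validation <- function(x, ...) {
  cat("End-to-end RPT dosimetry validation run\n")
  cat(sprintf("  administered %.0f MBq, scan at %.1f d, exposure %.2f d\n",
              x$config$a_admin_bq / 1e6, x$config$t_scan_days,
              x$config$t_exposed_days))
  cat(sprintf("  CF %.4g Bq/count; RC %.3f\n", x$cf$value, x$rc$value))
  cat(sprintf("  sphere conc: %.2f MBq/ml raw (%+.1f%% vs administered), %.2f MBq/ml corrected (%+.1f%%)\n",
              x$apparent_conc_bq_ml / 1e6, x$pct_vs_admin_no_pvc,
              x$corrected_conc_bq_ml / 1e6, x$pct_vs_admin_pvc))
  cat(sprintf("  cumulated activity: %.4g Bq s (ideal), %.4g Bq s (image)\n",
              x$a_tilde_ideal$a_tilde_bq_s, x$a_tilde_image$a_tilde_bq_s))
  cat("\n")
  print(x$table)
  invisible(x)
}

#' @export
summary.rpt_validation <- function(object, ...) {
  print(object)
  cat(sprintf("\nProbe mean energies (keV): %s\n",
              paste(sprintf("%.1f", object$mean_energies_kev), collapse = ", ")))
  cat(sprintf("Stage timings (s): %s\n",
              paste(sprintf("%s %.1f", names(object$timings), object$timings),
                    collapse = ", ")))
  invisible(object)
}

#' Materialize the bundled data fixtures
#'
#' Copies the decay table and TLD response curve, regenerates the photon
#' cross-section table from [xs_build_table()], and writes an example run
#' configuration, so a run depends on nothing outside the output directory.
#'
#' @param out_dir destination directory.
#' @return invisibly, the file paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (f in c("i131_decay.csv", "tld_response_synthetic.csv")) {
    src <- system.file("extdata", f, package = "rptdose", mustWork = TRUE)
    file.copy(src, file.path(out_dir, f), overwrite = TRUE)
    paths[f] <- file.path(out_dir, f)
  }
  xs_path <- file.path(out_dir, "photon_xs.csv")
  utils::write.csv(xs_build_table(), xs_path, row.names = FALSE)
  paths["photon_xs.csv"] <- xs_path
  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(run_config(), cfg_path)
  paths["run_config.yaml"] <- cfg_path
  invisible(paths)
}
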