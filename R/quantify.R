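#' Calibration factor
#' @param value Bq per count (> 0).
#' @param provenance free-text description of the calibration scan.
#' @return A `calibration_factor`.
#' @export
calibration_factor <- function(value, provenance = "") {
  stopifnot(value > 0)
  structure(list(value = value, provenance = provenance),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %.6g Bq/count (%s)\n", x$value, x$provenance))
  invisible(x)
}

#' Recovery coefficient
#' @param value dimensionless, in (0, 1].
#' @param object_volume_ml volume of the object it was measured for, ml.
#' @return A `recovery_coefficient`.
#' @export
recovery_coefficient <- function(value, object_volume_ml) {
  if (value <= 0 || value > 1) stop("recovery coefficient must be in (0, 1]")
  structure(list(value = value, object_volume_ml = object_volume_ml),
            class = "recovery_coefficient")
}

#' @export
print.recovery_coefficient <- function(x, ...) {
  cat(sprintf("<recovery_coefficient> %.4f (%.1f ml object)\n",
              x$value, x$object_volume_ml))
  invisible(x)
}

#' Estimate the calibration factor from a calibration scan
#'
#' Total true activity divided by total recorded counts over the image (or
#' an optional support mask). Unbiased for a uniform phantom imaged with a
#' count-conserving system.
#'
#' @param counts an `activity_grid` with unit `"counts"`.
#' @param truth the matching ground-truth `activity_grid` in Bq.
#' @param support optional logical array restricting both sums.
#' @return A `calibration_factor` in Bq per count.
#' @export
estimate_calibration_factor <- function(counts, truth, support = NULL) {
  stopifnot(counts$unit == "counts", truth$unit == "Bq")
  cv <- counts$values
  tv <- truth$values
  if (!is.null(support)) {
    cv <- cv[support]
    tv <- tv[support]
  }
  if (sum(tv) <= 0) stop("calibration truth has no activity")
  if (sum(cv) <= 0) stop("calibration scan has zero total counts")
  calibration_factor(sum(tv) / sum(cv), provenance = "uniform cylinder scan")
}

#' Convert counts to absolute activity
#' @param counts an `activity_grid` with unit `"counts"`.
#' @param cf a `calibration_factor`.
#' @return An `activity_grid` in Bq on the same grid.
#' @export
counts_to_activity <- function(counts, cf) {
  if (counts$unit != "counts") stop("input volume is not in counts")
  stopifnot(inherits(cf, "calibration_factor"))
  activity_grid(counts$grid, counts$values * cf$value, unit = "Bq")
}

#' Zero all voxels outside the source VOI
#'
#' Background masking before dose computation: voxels outside the VOI
#' support are set to zero, inside are unchanged. The fraction of activity
#' removed is attached as attribute `removed_fraction`.
#'
#' @param activity an `activity_grid`.
#' @param voi_weights fractional VOI weight array on the same grid; the
#'   support is `voi_weights > 0`.
#' @return The masked `activity_grid`.
#' @export
mask_background <- function(activity, voi_weights) {
  stopifnot(inherits(activity, "activity_grid"),
            all(dim(voi_weights) == activity$grid$shape))
  mask <- voi_weights > 0
  if (!any(mask)) stop("empty VOI")
  tot <- sum(activity$values)
  vals <- activity$values
  vals[!mask] <- 0
  out <- activity_grid(activity$grid, vals, unit = activity$unit)
  attr(out, "removed_fraction") <- if (tot > 0) (tot - sum(vals)) / tot else 0
  out
}

#' Apply a recovery coefficient to a VOI mean concentration
#'
#' Volume-level partial-volume correction: the corrected concentration is
#' `mean / rc`. Voxel-level correction is not attempted (the volume-averaged
#' coefficient carries no voxel-scale information).
#'
#' @param mean_conc_bq_ml apparent VOI mean concentration, Bq/ml.
#' @param rc a `recovery_coefficient`.
#' @return corrected concentration, Bq/ml.
#' @export
apply_recovery_coefficient <- function(mean_conc_bq_ml, rc) {
  stopifnot(inherits(rc, "recovery_coefficient"))
  mean_conc_bq_ml / rc$value
}

#' Rescale in-VOI voxels by a recovery coefficient
#'
#' Uniformly scales voxels in the VOI support by `1 / rc`, so the apparent
#' VOI mean equals the corrected value while the spatial pattern inside the
#' VOI is preserved.
#'
#' @inheritParams mask_background
#' @param rc a `recovery_coefficient`.
#' @return The rescaled `activity_grid`.
#' @export
apply_rc_to_image <- function(activity, voi_weights, rc) {
  stopifnot(inherits(rc, "recovery_coefficient"))
  mask <- voi_weights > 0
  vals <- activity$values
  vals[mask] <- vals[mask] / rc$value
  activity_grid(activity$grid, vals, unit = activity$unit)
}

#' Percent difference of a measured concentration vs the administered
#'
#' Reference is the administered activity divided by the sphere volume,
#' decay-corrected to scan time:
#' `ref = (A_admin / V) * exp(-lambda * t_scan)`; returns
#' `100 * (measured - ref) / ref`.
#'
#' @param measured_conc_bq_ml measured concentration, Bq/ml.
#' @param record an `administration_record` (uses `t_scan_days`).
#' @param nuclide a `nuclide_data`.
#' @param sphere_volume_ml source volume, ml.
#' @return percent difference.
#' @export
percent_vs_administered <- function(measured_conc_bq_ml, record, nuclide,
                                    sphere_volume_ml) {
  lambda <- decay_constant(nuclide$half_life_days)
  ref <- record$a_admin_bq / sphere_volume_ml * exp(-lambda * record$t_scan_days)
  100 * (measured_conc_bq_ml - ref) / ref
}

#' Resample an activity volume to another grid
#'
#' Interpolates the activity *concentration* (intensive) trilinearly onto
#' the target voxel centers, then converts back to per-voxel Bq on the
#' target voxel volume. Attribute `total_change` reports the relative
#' change in total activity (a diagnostic; trilinear interpolation of a
#' compactly supported field is not exactly conservative).
#'
#' @param activity an `activity_grid` in Bq.
#' @param target target `grid_spec` (must overlap).
#' @return An `activity_grid` in Bq on `target`.
#' @export
resample_to_grid <- function(activity, target) {
  stopifnot(inherits(activity, "activity_grid"), activity$unit == "Bq")
  conc <- activity$values / voxel_volume_ml(activity$grid)
  out <- resample_trilinear(conc, activity$grid, target, fill = 0)
  vals <- out * voxel_volume_ml(target)
  res <- activity_grid(target, vals, unit = "Bq")
  tot <- sum(activity$values)
  attr(res, "total_change") <- if (tot > 0) (sum(vals) - tot) / tot else 0
  res
}

#' CT numbers to mass density
#'
#' Piecewise-linear map anchored at -1000 -> 0.001 g/cm^3 (air) and
#' 0 -> 1.000 g/cm^3 (water), continuing with the same slope above water.
#' Values are clamped to the physical range with a warning.
#'
#' @param hu array of CT-number-like values (see [simulate_ct()]).
#' @return array of densities, g/cm^3.
#' @export
hu_to_density <- function(hu) {
  if (any(hu < -1100 | hu > 3000))
    warning("CT numbers outside [-1100, 3000] clamped to physical range")
  hu <- pmin(pmax(hu, -1000), 3000)
  0.001 + (hu + 1000) * 0.999 / 1000
}

#' Classify densities into transport materials
#'
#' Threshold map: density < 0.05 -> air, < 1.10 -> water, otherwise
#' acrylic. A simplified stand-in for full stoichiometric CT calibration,
#' sufficient for the three-material phantom.
#'
#' @param density array of densities, g/cm^3.
#' @param grid the `grid_spec` the densities live on.
#' @return A `material_grid` (with the bundled nominal densities).
#' @export
density_to_material <- function(density, grid) {
  codes <- array(MATERIAL_CODES[["water"]], dim = dim(density))
  codes[density < 0.05] <- MATERIAL_CODES[["air"]]
  codes[density >= 1.10] <- MATERIAL_CODES[["acrylic"]]
  material_grid(grid, codes)
}
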