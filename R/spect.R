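#' Synthetic SPECT/CT scanner model
#'
#' Image-formation surrogate for a reconstructed, calibrated SPECT volume:
#' the projection/reconstruction chain (OSEM, collimator-detector response,
#' scatter windows) is replaced by an image-domain isotropic Gaussian PSF,
#' a global sensitivity, and post-blur Poisson noise. This reproduces the
#' phenomena the downstream quantification must correct - partial volume
#' spill-out, count statistics, and the counts-to-activity calibration -
#' without projection-domain physics. Gibbs ringing is not modeled.
#'
#' @param psf_fwhm_mm isotropic Gaussian PSF full width at half maximum, mm
#'   (surrogate for the collimator-detector response at 364 keV; default
#'   12 mm, representative of I-131 high-energy-collimator SPECT).
#' @param sensitivity_cps_per_bq detected counts per second per Bq.
#' @param scan_duration_s total acquisition time, s (e.g. 120 projections
#'   x 30 s).
#' @param spect_grid reconstruction `grid_spec` (default 128^3 at 4.42 mm).
#' @param ct_grid CT `grid_spec` (default 247 x 253 x 52 at
#'   0.98 x 0.98 x 5.0 mm).
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed used whenever noise is enabled (mandatory for
#'   reproducible runs).
#' @return A `scanner_model`.
#' @export
scanner_model <- function(psf_fwhm_mm = 12,
                          sensitivity_cps_per_bq = 1.4e-5,
                          scan_duration_s = 3600,
                          spect_grid = grid_centered(c(128, 128, 128), rep(4.42, 3)),
                          ct_grid = grid_centered(c(247, 253, 52), c(0.98, 0.98, 5.0)),
                          noise = c("poisson", "none"),
                          seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(psf_fwhm_mm >= 0, sensitivity_cps_per_bq > 0, scan_duration_s > 0)
  if (noise == "poisson" && is.null(seed))
    stop("a seed is mandatory when Poisson noise is enabled")
  structure(list(psf_fwhm_mm = psf_fwhm_mm,
                 sensitivity_cps_per_bq = sensitivity_cps_per_bq,
                 scan_duration_s = scan_duration_s,
                 spect_grid = spect_grid, ct_grid = ct_grid,
                 noise = noise, seed = as.integer(seed)),
            class = "scanner_model")
}

#' @export
print.scanner_model <- function(x, ...) {
  cat(sprintf("<scanner_model> PSF FWHM %.1f mm, sensitivity %.3g cps/Bq, %g s scan, noise = %s (seed %d)\n",
              x$psf_fwhm_mm, x$sensitivity_cps_per_bq, x$scan_duration_s,
              x$noise, x$seed))
  invisible(x)
}

# evaluate fn with a local RNG state seeded by `seed`
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# separable Gaussian blur; sigma_vox in voxel units per axis. The kernel is
# normalized over its full (truncated at 4 sigma) support, so counts that
# blur past the grid edge are lost, as in a physical system.
gaussian_blur <- function(values, sigma_vox) {
  out <- values
  d <- dim(values)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 1e-9) next
    m <- max(1L, ceiling(4 * s))
    g <- exp(-0.5 * ((-m:m) / s)^2)
    g <- g / sum(g)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (j in -m:m) {
      i <- seq_len(n)
      tgt <- i + j
      ok <- tgt >= 1 & tgt <= n
      K[cbind(tgt[ok], i[ok])] <- g[j + m + 1]
    }
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

#' Simulate a SPECT counts volume
#'
#' Resamples the true activity (Bq) onto the SPECT grid conservatively,
#' applies the Gaussian PSF, scales by sensitivity x duration, and
#' Poisson-samples if noise is enabled. With noise off and unit
#' sensitivity-duration, blur-free output equals the resampled truth.
#'
#' @param truth an `activity_grid` in Bq (any grid overlapping the SPECT grid).
#' @param scanner a `scanner_model`.
#' @return An `activity_grid` with unit `"counts"` on the SPECT grid.
#' @export
simulate_spect <- function(truth, scanner) {
  stopifnot(inherits(truth, "activity_grid"), truth$unit == "Bq")
  g <- scanner$spect_grid
  vals <- resample_conservative(truth$values, truth$grid, g)
  attr(vals, "lost") <- NULL
  sig <- scanner$psf_fwhm_mm / 2.354820045 / g$spacing
  if (scanner$psf_fwhm_mm > 0) vals <- gaussian_blur(vals, sig)
  expected <- vals * scanner$sensitivity_cps_per_bq * scanner$scan_duration_s
  if (scanner$noise == "poisson") {
    counts <- with_seed(scanner$seed, function() {
      array(stats::rpois(length(expected), pmax(expected, 0)), dim = dim(expected))
    })
  } else {
    counts <- expected
  }
  activity_grid(g, counts, unit = "counts")
}

# water-anchored CT-number scale shared with hu_to_density(): -1000 at
# near-zero density, 0 at water, same slope above water
density_to_hu <- function(density) {
  (density - 1.0) * 1000 / 0.999
}

#' Simulate a CT-like density volume
#'
#' Maps per-voxel material density to a CT-number-like scale (water -> 0,
#' air -> -1000, linear in density) and resamples to the CT grid. Regions
#' outside the material grid are air.
#'
#' @param materials a `material_grid`.
#' @param scanner a `scanner_model` (provides the CT grid).
#' @return list with `grid` (the CT `grid_spec`) and `values` (HU array).
#' @export
simulate_ct <- function(materials, scanner) {
  stopifnot(inherits(materials, "material_grid"))
  dens <- array(materials$densities[materials$codes], dim = materials$grid$shape)
  hu <- density_to_hu(dens)
  out <- resample_trilinear(hu, materials$grid, scanner$ct_grid,
                            fill = density_to_hu(0.001))
  list(grid = scanner$ct_grid, values = out)
}

#' Simulate the uniform-cylinder calibration scan
#'
#' Fills a cylinder of the given volume uniformly at `uniform_conc_bq_ml`,
#' images it with the scanner model, and returns the counts volume together
#' with the ground-truth activity for calibration-factor estimation.
#'
#' @param cylinder_volume_l calibration cylinder volume, litres (default
#'   5.64 L).
#' @param uniform_conc_bq_ml activity concentration, Bq/ml (> 0).
#' @param scanner a `scanner_model`.
#' @param radius_mm cylinder radius, mm.
#' @return list with `counts` and `truth` (`activity_grid`s on the SPECT grid).
#' @export
calibration_scan <- function(cylinder_volume_l = 5.64, uniform_conc_bq_ml,
                             scanner, radius_mm = 108) {
  stopifnot(uniform_conc_bq_ml > 0)
  g <- scanner$spect_grid
  h <- cylinder_volume_l * 1e6 / (pi * radius_mm^2)
  ctr <- g$origin + (g$shape - 1) / 2 * g$spacing
  frac <- region_fraction(g, function(p) {
    (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 <= radius_mm^2 &
      abs(p[, 3] - ctr[3]) <= h / 2
  }, bbox = rbind(ctr - c(radius_mm, radius_mm, h / 2),
                  ctr + c(radius_mm, radius_mm, h / 2)), subsamples = 2L)
  truth <- activity_grid(g, frac * uniform_conc_bq_ml * voxel_volume_ml(g),
                         unit = "Bq")
  list(counts = simulate_spect(truth, scanner), truth = truth)
}

#' Measure a recovery coefficient for a sphere
#'
#' Simulates a sphere of known concentration with the scanner's PSF (noise
#' off: this is a careful calibration-type measurement), quantifies it in
#' the true analytic sphere VOI using the supplied calibration factor, and
#' returns RC = apparent mean concentration / true concentration.
#'
#' @param sphere_volume_ml sphere volume, ml (> 0).
#' @param scanner a `scanner_model`.
#' @param background_conc_bq_ml surrounding concentration, Bq/ml.
#' @param cf optional `calibration_factor`; default is the scanner's ideal
#'   factor 1 / (sensitivity x duration).
#' @param sphere_conc_bq_ml known sphere concentration, Bq/ml.
#' @return A `recovery_coefficient`.
#' @export
measure_recovery_coefficient <- function(sphere_volume_ml, scanner,
                                         background_conc_bq_ml = 0,
                                         cf = NULL,
                                         sphere_conc_bq_ml = 1e5) {
  stopifnot(sphere_volume_ml > 0)
  g <- scanner$spect_grid
  ctr <- g$origin + (g$shape - 1) / 2 * g$spacing
  r <- sphere_radius_from_volume(sphere_volume_ml)
  fine <- grid_centered(shape = rep(ceiling((2 * r + 8 * max(1, scanner$psf_fwhm_mm)) /
                                              (min(g$spacing) / 2)), 3),
                        spacing = rep(min(g$spacing) / 2, 3), center = ctr)
  frac <- sphere_voi_weights(fine, ctr, r, subsamples = 2L)
  vals <- frac * sphere_conc_bq_ml * voxel_volume_ml(fine)
  # conserve the analytic total exactly, as voxelize() does for the phantom
  vals <- vals * (sphere_conc_bq_ml * sphere_volume_ml / sum(vals))
  if (background_conc_bq_ml > 0)
    vals <- vals + (1 - frac) * background_conc_bq_ml * voxel_volume_ml(fine)
  truth <- activity_grid(fine, vals, unit = "Bq")
  sc <- scanner
  sc$noise <- "none"
  counts <- simulate_spect(truth, sc)
  cf_val <- if (is.null(cf)) 1 / (scanner$sensitivity_cps_per_bq * scanner$scan_duration_s)
            else cf$value
  act_bq <- counts$values * cf_val
  voi <- sphere_support_mask(g, ctr, r)
  apparent <- apparent_mean_conc(act_bq, voi, sphere_volume_ml)
  recovery_coefficient(min(apparent / sphere_conc_bq_ml, 1), sphere_volume_ml)
}

#' Sphere quantification support on a grid
#'
#' Every voxel that can hold content of the rasterized sphere: voxel center
#' within `radius + half the voxel diagonal` (which also absorbs
#' nearest-neighbor reassignment from a twice-finer rasterization grid). A
#' guaranteed superset, so a blur-free rasterized sphere is quantified
#' exactly;
#' the same support is used when measuring recovery coefficients and when
#' quantifying, making any support-definition bias cancel in the corrected
#' concentration.
#'
#' @inheritParams sphere_voi_weights
#' @return logical 3-D array.
#' @export
sphere_support_mask <- function(grid, center, radius) {
  reff <- radius + 0.5 * sqrt(sum(grid$spacing^2))
  sphere_voi_weights(grid, center, reff, subsamples = 1L) > 0
}

# Apparent mean concentration: total activity over the VOI support divided
# by the analytic VOI volume (conservation-based estimator).
apparent_mean_conc <- function(activity_bq, support, volume_ml) {
  if (sum(support > 0) == 0) stop("empty VOI")
  sum(activity_bq[support > 0]) / volume_ml
}
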