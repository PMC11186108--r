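#' Stylized phantom configuration
#'
#' Describes the measurement phantom: a water-filled cylinder (Jaszczak
#' type), a hollow source sphere filled with radionuclide solution, and a
#' set of acrylic TLD probes, each a vertical rod whose cap holds the TLD
#' stack. Probe positions are the world coordinates of the TLD/scorer
#' centers; the rod hangs below them.
#'
#' The defaults emulate a 6.4 L flangeless Jaszczak cylinder (radius
#' 10.8 cm, height solved from the volume) with a 16 ml sphere and six
#' probes at staggered radial distances 2.4-6.2 cm from the sphere center,
#' spanning roughly a tenfold dose range.
#'
#' @param cylinder_volume_l cylinder volume, litres.
#' @param cylinder_radius_mm cylinder radius, mm (height is derived).
#' @param sphere_volume_ml source sphere volume, ml.
#' @param sphere_center sphere center, world mm.
#' @param probe_positions matrix (n x 3) of TLD-stack centers, world mm.
#' @param probe_rod_diameter_mm acrylic rod diameter, mm.
#' @param probe_post_height_mm rod post height, mm.
#' @param probe_cap_height_mm rod cap height, mm (post and cap are merged
#'   into a single rod for voxelization).
#' @param materials named list mapping regions (`background`, `sphere`,
#'   `probe`, `outside`) to material names.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(cylinder_volume_l = 6.4,
                           cylinder_radius_mm = 108,
                           sphere_volume_ml = 16,
                           sphere_center = c(0, 0, 20),
                           probe_positions = default_probe_positions(sphere_center),
                           probe_rod_diameter_mm = 12.7,
                           probe_post_height_mm = 96.5,
                           probe_cap_height_mm = 15.2,
                           materials = list(background = "water", sphere = "water",
                                            probe = "acrylic", outside = "air")) {
  stopifnot(cylinder_volume_l > 0, cylinder_radius_mm > 0, sphere_volume_ml > 0)
  probe_positions <- as.matrix(probe_positions)
  stopifnot(ncol(probe_positions) == 3)
  cfg <- structure(list(
    cylinder_volume_l = cylinder_volume_l,
    cylinder_radius_mm = cylinder_radius_mm,
    cylinder_height_mm = cylinder_volume_l * 1e6 / (pi * cylinder_radius_mm^2),
    sphere_volume_ml = sphere_volume_ml,
    sphere_radius_mm = sphere_radius_from_volume(sphere_volume_ml),
    sphere_center = as.numeric(sphere_center),
    probe_positions = probe_positions,
    probe_rod_diameter_mm = probe_rod_diameter_mm,
    probe_post_height_mm = probe_post_height_mm,
    probe_cap_height_mm = probe_cap_height_mm,
    materials = materials), class = "phantom_config")
  cfg
}

#' Sphere radius from volume
#' @param volume_ml sphere volume in ml.
#' @return radius in mm.
#' @export
sphere_radius_from_volume <- function(volume_ml) {
  (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
}

#' Default TLD probe positions
#'
#' Six scorer centers around the source sphere at staggered distances
#' (24-62 mm) and azimuths, chosen to span roughly a tenfold photon dose
#' range in water. Positions are configuration, not physics: real setups
#' mount probes wherever the phantom lid allows.
#'
#' @param sphere_center sphere center, world mm.
#' @return 6 x 3 matrix of world mm coordinates.
#' @export
default_probe_positions <- function(sphere_center = c(0, 0, 20)) {
  d <- c(24, 30, 36, 44, 52, 62)
  th <- c(0, 60, 120, 180, 240, 300) * pi / 180
  zf <- c(0, 0.15, -0.15, 0.2, 0, -0.2)
  u <- cbind(cos(th) * sqrt(1 - zf^2), sin(th) * sqrt(1 - zf^2), zf)
  unname(sweep(u * d, 2, sphere_center, "+"))
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %.2f L cylinder (r = %.1f mm, h = %.1f mm)\n",
              x$cylinder_volume_l, x$cylinder_radius_mm, x$cylinder_height_mm))
  cat(sprintf("  source sphere: %.1f ml (r = %.2f mm) at (%.1f, %.1f, %.1f) mm\n",
              x$sphere_volume_ml, x$sphere_radius_mm,
              x$sphere_center[1], x$sphere_center[2], x$sphere_center[3]))
  cat(sprintf("  %d probes, rod diameter %.1f mm\n",
              nrow(x$probe_positions), x$probe_rod_diameter_mm))
  invisible(x)
}

#' Analytic phantom geometry
#'
#' Validates a [phantom_config()] and returns the constructive geometry:
#' cylinder, source sphere and probe rods with material assignments, plus a
#' vectorized point-classification function. Fails if the sphere is not
#' fully inside the cylinder or a probe rod intersects the source sphere
#' (contradictory material assignment).
#'
#' @param config a `phantom_config`.
#' @return A `phantom` object.
#' @export
build_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  r_cyl <- config$cylinder_radius_mm
  h_cyl <- config$cylinder_height_mm
  sc <- config$sphere_center
  r_s <- config$sphere_radius_mm
  if (sqrt(sum(sc[1:2]^2)) + r_s > r_cyl || abs(sc[3]) + r_s > h_cyl / 2)
    stop("source sphere is not fully inside the cylinder")
  rod_r <- config$probe_rod_diameter_mm / 2
  rod_len <- config$probe_post_height_mm + config$probe_cap_height_mm
  rods <- lapply(seq_len(nrow(config$probe_positions)), function(k) {
    p <- config$probe_positions[k, ]
    top <- p[3] + config$probe_cap_height_mm / 2
    list(x = p[1], y = p[2], z_top = top,
         z_bot = max(top - rod_len, -h_cyl / 2), r = rod_r)
  })
  for (rod in rods) {
    dxy <- sqrt((rod$x - sc[1])^2 + (rod$y - sc[2])^2)
    dz <- max(0, sc[3] - rod$z_top, rod$z_bot - sc[3])
    if (sqrt(dxy^2 + dz^2) - rod$r < r_s)
      stop("probe rod intersects the source sphere: contradictory materials")
  }
  structure(list(config = config, rods = rods,
                 cylinder = list(r = r_cyl, h = h_cyl),
                 sphere = list(center = sc, r = r_s)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> analytic geometry\n")
  print(x$config)
  invisible(x)
}

# Material codes: 1 = air, 2 = water, 3 = acrylic (indexes the density and
# cross-section tables). Probes take precedence over water; everything
# outside the cylinder is air.
MATERIAL_CODES <- c(air = 1L, water = 2L, acrylic = 3L)

#' Bundled material densities (g/cm^3)
#' @return named numeric vector indexed by material code order (air, water,
#'   acrylic).
#' @export
material_densities <- function() c(air = 0.0012, water = 1.000, acrylic = 1.190)

# classify world points (n x 3) into material codes
phantom_material_at <- function(phantom, pts) {
  code <- rep(MATERIAL_CODES[[phantom$config$materials$outside]], nrow(pts))
  in_cyl <- pts[, 1]^2 + pts[, 2]^2 <= phantom$cylinder$r^2 &
    abs(pts[, 3]) <= phantom$cylinder$h / 2
  code[in_cyl] <- MATERIAL_CODES[[phantom$config$materials$background]]
  for (rod in phantom$rods) {
    in_rod <- (pts[, 1] - rod$x)^2 + (pts[, 2] - rod$y)^2 <= rod$r^2 &
      pts[, 3] <= rod$z_top & pts[, 3] >= rod$z_bot
    code[in_rod] <- MATERIAL_CODES[[phantom$config$materials$probe]]
  }
  code
}

#' Material grid container
#' @param grid a `grid_spec`.
#' @param codes integer array of material codes matching `grid$shape`.
#' @param densities numeric vector of g/cm^3 indexed by code.
#' @return A `material_grid`.
#' @export
material_grid <- function(grid, codes, densities = material_densities()) {
  stopifnot(all(dim(codes) == grid$shape))
  if (any(!codes %in% seq_along(densities))) stop("unknown material code")
  if (any(densities <= 0)) stop("densities must be positive")
  structure(list(grid = grid, codes = codes, densities = densities),
            class = "material_grid")
}

#' Activity grid container
#' @param grid a `grid_spec`.
#' @param values numeric array matching `grid$shape`.
#' @param unit one of `"Bq"`, `"Bq/ml"`, `"counts"`.
#' @return An `activity_grid`.
#' @export
activity_grid <- function(grid, values, unit = c("Bq", "Bq/ml", "counts")) {
  unit <- match.arg(unit)
  stopifnot(all(dim(values) == grid$shape))
  if (any(values < 0)) stop("activity values must be >= 0")
  if (!is.finite(sum(values))) stop("total activity must be finite")
  structure(list(grid = grid, values = values, unit = unit),
            class = "activity_grid")
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("<activity_grid> unit %s, total %.6g, max %.6g\n",
              x$unit, sum(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Voxelize the analytic phantom onto a grid
#'
#' Materials by majority vote over `subsamples^3` regular sample points per
#' voxel; activity apportioned by the fraction of sample points inside the
#' source sphere, rescaled so the voxelized total equals `total_bq` exactly.
#'
#' @param phantom a `phantom` from [build_phantom()].
#' @param grid target `grid_spec`.
#' @param total_bq total source activity to distribute (Bq).
#' @param subsamples sample points per axis per voxel.
#' @return list with elements `materials` (a `material_grid`) and `activity`
#'   (an `activity_grid`, unit Bq).
#' @export
voxelize <- function(phantom, grid, total_bq, subsamples = 2L) {
  s <- as.integer(subsamples)
  stopifnot(s >= 1L, total_bq >= 0)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  bb_lo <- c(-phantom$cylinder$r, -phantom$cylinder$r, -phantom$cylinder$h / 2)
  bb_hi <- -bb_lo
  if (any(lo > bb_lo) || any(hi < bb_hi))
    warning("grid does not cover the phantom bounding box")
  nmat <- length(material_densities())
  votes <- vapply(seq_len(nmat), function(i) numeric(prod(grid$shape)),
                  numeric(prod(grid$shape)))
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  n <- grid$shape
  P <- cbind(rep(cx, times = n[2] * n[3]),
             rep(rep(cy, each = n[1]), times = n[3]),
             rep(cz, each = n[1] * n[2]))
  for (ox in off) for (oy in off) for (oz in off) {
    q <- P
    q[, 1] <- q[, 1] + ox * grid$spacing[1]
    q[, 2] <- q[, 2] + oy * grid$spacing[2]
    q[, 3] <- q[, 3] + oz * grid$spacing[3]
    cd <- phantom_material_at(phantom, q)
    for (i in seq_len(nmat)) votes[, i] <- votes[, i] + (cd == i)
  }
  codes <- array(max.col(votes, ties.method = "first"), dim = n)
  frac <- sphere_voi_weights(grid, phantom$sphere$center, phantom$sphere$r,
                             subsamples = s)
  # the solution lives in the sphere: boundary voxels voted to probe
  # acrylic (or air) carry no activity; rescaling below keeps the total
  frac[codes != MATERIAL_CODES[[phantom$config$materials$sphere]]] <- 0
  tot <- sum(frac)
  vals <- if (tot > 0 && total_bq > 0) frac * (total_bq / tot) else frac * 0
  list(materials = material_grid(grid, codes),
       activity = activity_grid(grid, vals, unit = "Bq"))
}
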