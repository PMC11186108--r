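#' Regular 3-D voxel grid geometry
#'
#' A `grid_spec` ties a 3-D array to world coordinates: right-handed, mm
#' units, with `origin` the world coordinate of the *center* of the first
#' voxel (array index `[1,1,1]`). Two grids with different spacings
#' co-register through these world coordinates.
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param spacing numeric triple, voxel edge lengths in mm (all > 0).
#' @param origin numeric triple, world mm coordinate of the first voxel center.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape entries must be >= 1")
  if (any(spacing <= 0)) stop("grid spacings must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' Grid centered on a world point
#'
#' Convenience constructor: places the grid so its geometric center sits at
#' `center`.
#'
#' @inheritParams grid_spec
#' @param center world mm coordinate of the grid center.
#' @return A `grid_spec`.
#' @export
grid_centered <- function(shape, spacing, center = c(0, 0, 0)) {
  origin <- center - (shape - 1) / 2 * spacing
  grid_spec(shape, spacing, origin)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f; voxel volume %.4g ml\n",
              x$origin[1], x$origin[2], x$origin[3], voxel_volume_ml(x)))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param grid a `grid_spec`.
#' @return voxel volume in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

#' Voxel center world coordinates along one axis
#' @param grid a `grid_spec`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of world mm coordinates.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# continuous (1-based) array index of world points; pts is n x 3
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

# world coordinate of 1-based (possibly fractional) indices; idx is n x 3
index_to_world <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

grids_overlap <- function(a, b) {
  lo_a <- a$origin - a$spacing / 2
  hi_a <- a$origin + (a$shape - 0.5) * a$spacing
  lo_b <- b$origin - b$spacing / 2
  hi_b <- b$origin + (b$shape - 0.5) * b$spacing
  all(lo_a < hi_b & lo_b < hi_a)
}

#' Trilinear interpolation of a volume onto another grid
#'
#' Interpolates voxel-center values of `values` (defined on `grid_from`) at
#' the voxel centers of `grid_to`. Points outside the source grid get
#' `fill`. Intended for intensive quantities (concentrations, HU); use
#' [resample_conservative()] for extensive ones (counts, Bq).
#'
#' @param values 3-D array matching `grid_from$shape`.
#' @param grid_from,grid_to `grid_spec` objects; must overlap.
#' @param fill value assigned outside the source grid (default 0).
#' @return 3-D array with `grid_to$shape`.
#' @export
resample_trilinear <- function(values, grid_from, grid_to, fill = 0) {
  stopifnot(all(dim(values) == grid_from$shape))
  if (!grids_overlap(grid_from, grid_to)) stop("grids do not overlap")
  xs <- (axis_coords(grid_to, 1) - grid_from$origin[1]) / grid_from$spacing[1] + 1
  ys <- (axis_coords(grid_to, 2) - grid_from$origin[2]) / grid_from$spacing[2] + 1
  zs <- (axis_coords(grid_to, 3) - grid_from$origin[3]) / grid_from$spacing[3] + 1
  n <- grid_to$shape
  ix <- rep(xs, times = n[2] * n[3])
  iy <- rep(rep(ys, each = n[1]), times = n[3])
  iz <- rep(zs, each = n[1] * n[2])
  out <- trilinear_gather(values, grid_from$shape, ix, iy, iz, fill)
  array(out, dim = n)
}

# gather with trilinear weights at continuous 1-based indices
trilinear_gather <- function(values, shp, ix, iy, iz, fill = 0) {
  inside <- ix >= 1 & ix <= shp[1] & iy >= 1 & iy <= shp[2] & iz >= 1 & iz <= shp[3]
  out <- rep(as.numeric(fill), length(ix))
  if (!any(inside)) return(out)
  ix <- ix[inside]; iy <- iy[inside]; iz <- iz[inside]
  x0 <- pmin(pmax(floor(ix), 1), shp[1] - 1); fx <- pmin(pmax(ix - x0, 0), 1)
  y0 <- pmin(pmax(floor(iy), 1), shp[2] - 1); fy <- pmin(pmax(iy - y0, 0), 1)
  z0 <- pmin(pmax(floor(iz), 1), shp[3] - 1); fz <- pmin(pmax(iz - z0, 0), 1)
  if (shp[1] == 1L) { x0 <- rep(1, length(ix)); fx <- 0 }
  if (shp[2] == 1L) { y0 <- rep(1, length(iy)); fy <- 0 }
  if (shp[3] == 1L) { z0 <- rep(1, length(iz)); fz <- 0 }
  lin <- function(a, b, c) a + (b - 1) * shp[1] + (c - 1) * shp[1] * shp[2]
  v <- values
  acc <- v[lin(x0,     y0,     z0    )] * (1 - fx) * (1 - fy) * (1 - fz) +
         v[lin(x0 + 1, y0,     z0    )] * fx       * (1 - fy) * (1 - fz) +
         v[lin(x0,     y0 + 1, z0    )] * (1 - fx) * fy       * (1 - fz) +
         v[lin(x0 + 1, y0 + 1, z0    )] * fx       * fy       * (1 - fz) +
         v[lin(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
         v[lin(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
         v[lin(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
         v[lin(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
  out[inside] <- acc
  out
}

#' Sum-preserving resampling of an extensive volume
#'
#' Moves each source voxel's content to the target voxel whose center is
#' nearest to the source voxel center. Totals are conserved exactly for
#' source voxels that land inside the target grid.
#'
#' @inheritParams resample_trilinear
#' @return 3-D array with `grid_to$shape`; `attr(.,"lost")` holds the total
#'   that fell outside the target grid.
#' @export
resample_conservative <- function(values, grid_from, grid_to) {
  stopifnot(all(dim(values) == grid_from$shape))
  if (!grids_overlap(grid_from, grid_to)) stop("grids do not overlap")
  n <- grid_from$shape; m <- grid_to$shape
  ix <- round((axis_coords(grid_from, 1) - grid_to$origin[1]) / grid_to$spacing[1]) + 1
  iy <- round((axis_coords(grid_from, 2) - grid_to$origin[2]) / grid_to$spacing[2]) + 1
  iz <- round((axis_coords(grid_from, 3) - grid_to$origin[3]) / grid_to$spacing[3]) + 1
  IX <- rep(ix, times = n[2] * n[3])
  IY <- rep(rep(iy, each = n[1]), times = n[3])
  IZ <- rep(iz, each = n[1] * n[2])
  keep <- IX >= 1 & IX <= m[1] & IY >= 1 & IY <= m[2] & IZ >= 1 & IZ <= m[3]
  lin <- IX[keep] + (IY[keep] - 1) * m[1] + (IZ[keep] - 1) * m[1] * m[2]
  vals <- as.numeric(values)[keep]
  out <- numeric(prod(m))
  agg <- rowsum(vals, group = lin)
  out[as.integer(rownames(agg))] <- agg
  res <- array(out, dim = m)
  attr(res, "lost") <- sum(values) - sum(vals)
  res
}

#' Fractional sphere membership weights on a grid
#'
#' For each voxel, the fraction of `subsamples^3` regularly spaced sample
#' points that fall inside the sphere. Used both to rasterize the source VOI
#' and to apportion activity.
#'
#' @param grid a `grid_spec`.
#' @param center sphere center, world mm.
#' @param radius sphere radius, mm.
#' @param subsamples sample points per axis per voxel (>= 1).
#' @return 3-D array of weights in \[0, 1\].
#' @export
sphere_voi_weights <- function(grid, center, radius, subsamples = 3L) {
  region_fraction(grid, function(p) {
    rowSums(sweep(p, 2, center, "-")^2) <= radius^2
  }, bbox = rbind(center - radius, center + radius), subsamples = subsamples)
}

#' Fractional axis-aligned box membership weights
#'
#' @inheritParams sphere_voi_weights
#' @param center box center, world mm.
#' @param edge box edge length(s), mm (scalar or triple).
#' @return 3-D array of weights in \[0, 1\].
#' @export
box_voi_weights <- function(grid, center, edge, subsamples = 3L) {
  h <- rep(edge, length.out = 3) / 2
  region_fraction(grid, function(p) {
    d <- abs(sweep(p, 2, center, "-"))
    d[, 1] <= h[1] & d[, 2] <= h[2] & d[, 3] <= h[3]
  }, bbox = rbind(center - h, center + h), subsamples = subsamples)
}

# fraction of subsample points satisfying `inside(points)` per voxel,
# evaluated only over the voxels touching `bbox` (2 x 3 matrix lo/hi)
region_fraction <- function(grid, inside, bbox, subsamples = 3L) {
  s <- as.integer(subsamples)
  stopifnot(s >= 1L)
  w <- array(0, dim = grid$shape)
  rng <- lapply(1:3, function(a) {
    lo <- max(1, floor((bbox[1, a] - grid$origin[a]) / grid$spacing[a]))
    hi <- min(grid$shape[a],
              ceiling((bbox[2, a] - grid$origin[a]) / grid$spacing[a]) + 2)
    if (lo > hi) integer(0) else seq(lo, hi)
  })
  if (any(lengths(rng) == 0)) return(w)
  off <- ((seq_len(s) - 0.5) / s - 0.5)  # sub-voxel offsets in voxel units
  cx <- grid$origin[1] + (rng[[1]] - 1) * grid$spacing[1]
  cy <- grid$origin[2] + (rng[[2]] - 1) * grid$spacing[2]
  cz <- grid$origin[3] + (rng[[3]] - 1) * grid$spacing[3]
  nb <- c(length(cx), length(cy), length(cz))
  acc <- numeric(prod(nb))
  P <- cbind(rep(cx, times = nb[2] * nb[3]),
             rep(rep(cy, each = nb[1]), times = nb[3]),
             rep(cz, each = nb[1] * nb[2]))
  for (ox in off) for (oy in off) for (oz in off) {
    q <- P
    q[, 1] <- q[, 1] + ox * grid$spacing[1]
    q[, 2] <- q[, 2] + oy * grid$spacing[2]
    q[, 3] <- q[, 3] + oz * grid$spacing[3]
    acc <- acc + inside(q)
  }
  w[rng[[1]], rng[[2]], rng[[3]]] <- array(acc / s^3, dim = nb)
  w
}

#' Weighted mean of a volume over a VOI
#' @param values 3-D array.
#' @param weights 3-D array of VOI weights, same shape.
#' @return scalar weighted mean.
#' @export
voi_mean <- function(values, weights) {
  stopifnot(all(dim(values) == dim(weights)))
  sw <- sum(weights)
  if (sw <= 0) stop("empty VOI")
  sum(values * weights) / sw
}
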