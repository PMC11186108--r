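# shared small fixtures, built in code

fixture_xs <- local({
  xs <- NULL
  function() {
    if (is.null(xs)) xs <<- cross_section_table()
    xs
  }
})

fixture_nuclide <- local({
  n <- NULL
  function() {
    if (is.null(n)) n <<- i131_nuclide()
    n
  }
})

# uniform water block
water_block <- function(shape = c(13, 13, 13), spacing = 5) {
  g <- grid_centered(shape, rep(spacing, 3))
  material_grid(g, array(2L, g$shape))
}

# independent ray-marching oracle: optical depth along a straight ray
# through a voxel grid (fine-step quadrature; deliberately naive)
ray_march_optical_depth <- function(materials, xs, start, dir, energy_kev,
                                    step_mm = 0.05) {
  g <- materials$grid
  mu_by_code <- vapply(seq_along(materials$densities), function(code) {
    name <- names(materials$densities)[code]
    rptdose:::xs_interp(xs, name, energy_kev, "mu_rho_total") *
      materials$densities[code] / 10  # mm^-1
  }, numeric(1))
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$shape - 0.5) * g$spacing
  tau <- 0
  p <- start
  repeat {
    p <- p + dir * step_mm
    if (any(p < lo) || any(p > hi)) break
    idx <- pmin(pmax(floor((p - lo) / g$spacing) + 1, 1), g$shape)
    tau <- tau + mu_by_code[materials$codes[idx[1], idx[2], idx[3]]] * step_mm
  }
  tau
}

# numeric Klein-Nishina expectations (independent of the C++ sampler)
kn_mean_eps_numeric <- function(energy_kev) {
  k <- energy_kev / 510.99895
  e0 <- 1 / (1 + 2 * k)
  dkn <- function(eps) {
    t <- (1 - eps) / (k * eps)
    (1 / eps + eps) * (1 - eps * t * (2 - t) / (1 + eps^2))
  }
  stats::integrate(function(e) e * dkn(e), e0, 1)$value /
    stats::integrate(dkn, e0, 1)$value
}
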