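test_that("emission sampling follows the line yields and is isotropic", {
  one <- nuclide_data("mono", 1, data.frame(energy_kev = 364.489, yield = 1),
                      beta_mean_kev = 0)
  src <- list(center = c(0, 0, 0), radius_mm = 10)
  set.seed(11)
  em <- sample_emission(one, 1e4, src)
  expect_true(all(em$energy_kev == 364.489))
  nuc <- fixture_nuclide()
  set.seed(12)
  em2 <- sample_emission(nuc, 1e5, src)
  y <- nuc$photon_lines$yield[nuc$photon_lines$energy_kev == 364.489]
  n364 <- sum(em2$energy_kev == 364.489)
  expect_lt(abs(n364 - 1e5 * y), 3 * sqrt(1e5 * y * (1 - y)))
  norms <- sqrt(rowSums(em2$dir^2))
  expect_true(all(abs(norms - 1) < 1e-12))
  expect_true(all(abs(colMeans(em2$dir)) < 3 / sqrt(3 * 1e5) * 2))
  # positions inside the sphere
  expect_true(all(rowSums(em2$pos^2) <= 10^2 + 1e-9))
  empty <- nuclide_data("none", 1, data.frame(energy_kev = numeric(0),
                                              yield = numeric(0)),
                        beta_mean_kev = 0)
  expect_error(sample_emission(empty, 10, src), "empty emission")
})

test_that("uncollided transmission matches the ray-marching oracle on a heterogeneous grid", {
  xs <- fixture_xs()
  set.seed(21)
  g <- grid_spec(c(5, 5, 5), c(10, 30, 30), origin = c(5, -60, -60))
  codes <- array(sample(c(1L, 2L, 3L), 125, replace = TRUE,
                        prob = c(0.2, 0.5, 0.3)), g$shape)
  mg <- material_grid(g, codes)
  n <- 1e5
  # rays through random (y, z) entry points, along +x
  set.seed(22)
  ys <- runif(25, -55, 55)
  zs <- runif(25, -55, 55)
  idx <- rep(1:25, each = n / 25)
  starts <- cbind(0.001, ys[idx], zs[idx])
  prep <- rptdose:::xs_prepare(xs, material_densities())
  set.seed(23)
  res <- rptdose:::.transport_batch(starts,
                                    matrix(rep(c(1, 0, 0), each = n), n, 3),
                                    rep(364.489, n),
                                    as.integer(codes), g$shape, g$spacing,
                                    g$origin, prep$egrid, prep$mu, prep$fpe,
                                    prep$mumax, 10, matrix(0, 0, 3), 1, 5, 146L,
                                    rep(0.5, length(prep$egrid)))
  taus <- vapply(seq_along(ys), function(i)
    ray_march_optical_depth(mg, xs, c(0.001, ys[i], zs[i]), c(1, 0, 0),
                            364.489), numeric(1))
  p_expect <- mean(exp(-taus))
  p_mc <- res$n_uncollided / n
  se <- sqrt(p_expect * (1 - p_expect) / n) +
    sd(exp(-taus)) / sqrt(length(taus)) * 0  # binomial error dominates
  expect_lt(abs(p_mc - p_expect), 3 * se + 0.004)
})

test_that("energy is conserved exactly in every transport configuration", {
  xs <- fixture_xs()
  nuc <- fixture_nuclide()
  configs <- list(
    list(mat = water_block(), hist = 2e4),
    list(mat = {
      g <- grid_centered(c(9, 9, 9), rep(8, 3))
      codes <- array(2L, g$shape)
      codes[1:3, , ] <- 1L
      codes[7:9, , ] <- 3L
      material_grid(g, codes)
    }, hist = 2e4))
  for (cfg in configs) {
    d <- run_dose(list(center = c(0, 0, 0), radius_mm = 8), cfg$mat, nuc, xs,
                  histories = cfg$hist, seed = 5, n_batches = 4L)
    eb <- d$energy_balance
    expect_equal(eb$deposited_kev + eb$escaped_kev, eb$emitted_kev,
                 tolerance = 1e-10)
  }
})

test_that("uniform beta-only activity reproduces the equilibrium dose closed form", {
  xs <- fixture_xs()
  g <- grid_centered(c(13, 13, 13), rep(5, 3))
  mg <- material_grid(g, array(2L, g$shape))
  conc_bq_ml <- 1e6
  act <- activity_grid(g, array(conc_bq_ml * voxel_volume_ml(g), g$shape),
                       unit = "Bq")
  beta_only <- nuclide_data("beta", 8.0197,
                            data.frame(energy_kev = 364.489, yield = 0),
                            beta_mean_kev = 191.9)
  d <- run_dose(act, mg, beta_only, xs, histories = 1e4, seed = 3,
                n_batches = 2L)
  mass_kg <- 1.0 * prod(g$spacing) / 1000 / 1000
  expected <- 191.9 * 1.602176634e-16 / (prod(g$shape) * mass_kg)
  interior <- d$dose[3:11, 3:11, 3:11]
  expect_true(all(abs(interior - expected) / expected < 0.005))
})

test_that("Klein-Nishina sampling matches the analytic mean scattered energy", {
  set.seed(31)
  s <- rptdose:::.kn_sample(364.489, 1e6)
  expect_equal(mean(s), kn_mean_eps_numeric(364.489), tolerance = 0.005)
  k <- 364.489 / 510.99895
  expect_true(all(s >= 1 / (1 + 2 * k) - 1e-12 & s <= 1 + 1e-12))
})

test_that("seeded dose runs are bit-identical", {
  xs <- fixture_xs()
  nuc <- fixture_nuclide()
  mg <- water_block(c(11, 11, 11), 8)
  src <- list(center = c(0, 0, 0), radius_mm = 10)
  d1 <- run_dose(src, mg, nuc, xs, histories = 1e4, seed = 42, n_batches = 2L)
  d2 <- run_dose(src, mg, nuc, xs, histories = 1e4, seed = 42, n_batches = 2L)
  expect_identical(d1$dose, d2$dose)
  expect_identical(d1$rel_uncertainty, d2$rel_uncertainty)
})

test_that("batch uncertainty scales as one over the square root of histories", {
  xs <- fixture_xs()
  nuc <- fixture_nuclide()
  mg <- water_block(c(15, 15, 15), 8)
  src <- list(center = c(0, 0, 0), radius_mm = 10)
  hists <- c(5e3, 2e4, 8e4, 3.2e5)
  uncs <- vapply(hists, function(h) {
    d <- run_dose(src, mg, nuc, xs, histories = h, seed = 7, n_batches = 10L)
    roi_mean_dose(d, c(40, 0, 0), edge_mm = 16)$rel_uncertainty
  }, numeric(1))
  fit <- lm(log(uncs) ~ log(hists))
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.1)
})

test_that("fluence falls off as inverse square in a near-transparent medium", {
  xs <- fixture_xs()
  g <- grid_centered(c(23, 23, 23), rep(10, 3))
  mg <- material_grid(g, array(1L, g$shape))  # air
  one <- nuclide_data("mono", 1, data.frame(energy_kev = 364.489, yield = 1),
                      beta_mean_kev = 0)
  src <- list(center = c(0, 0, 0), radius_mm = 0.5)  # point-like
  sc <- scorer_spec(rbind(c(50, 0, 0), c(100, 0, 0)), edge_mm = 20)
  d <- run_dose(src, mg, one, xs, scorers = sc, histories = 4e5, seed = 9,
                n_batches = 10L)
  phi <- vapply(d$spectra, function(s) sum(s$values), numeric(1))
  scaled <- phi * c(5^2, 10^2)
  expect_equal(scaled[1] / scaled[2], 1, tolerance = 0.1)
})

test_that("mean energy reduces single and double occupied bins correctly", {
  sp1 <- fluence_spectrum(seq(0, 730, by = 5),
                          c(rep(0, 72), 1, rep(0, 73)))
  expect_equal(mean_energy(sp1), 362.5)
  v <- rep(0, 146)
  v[10] <- 1
  v[20] <- 1
  sp2 <- fluence_spectrum(seq(0, 730, by = 5), v)
  expect_equal(mean_energy(sp2), (47.5 + 97.5) / 2)
  expect_error(mean_energy(fluence_spectrum(seq(0, 730, by = 5), rep(0, 146))),
               "all-zero")
})

test_that("a vacuum-like medium tallies the full chord through a scorer", {
  xs <- fixture_xs()
  g <- grid_centered(c(21, 21, 21), rep(10, 3))
  mg <- material_grid(g, array(1L, g$shape))  # air, nearly transparent
  prep <- rptdose:::xs_prepare(xs, material_densities())
  n <- 200
  pos <- cbind(rep(-104.9, n), 0, 0)
  dir <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  set.seed(13)
  res <- rptdose:::.transport_batch(pos, dir, rep(364.489, n),
                                    as.integer(mg$codes), g$shape, g$spacing,
                                    g$origin, prep$egrid, prep$mu, prep$fpe,
                                    prep$mumax, 10,
                                    matrix(c(0, 0, 0), 1, 3), 5, 5, 146L,
                                    rep(0.5, length(prep$egrid)))
  total_track <- sum(res$spectra_mm)
  expect_equal(total_track / n, 5, tolerance = 0.02)
})

test_that("absolute dose maps scale linearly with cumulated activity", {
  xs <- fixture_xs()
  nuc <- fixture_nuclide()
  mg <- water_block(c(9, 9, 9), 8)
  d <- run_dose(list(center = c(0, 0, 0), radius_mm = 8), mg, nuc, xs,
                histories = 5e3, seed = 2, n_batches = 2L)
  z <- absolute_dose_map(d, 0)
  expect_true(all(z$dose == 0))
  a <- absolute_dose_map(d, 5.737e14)
  b <- absolute_dose_map(d, 2 * 5.737e14)
  expect_equal(b$dose, 2 * a$dose)
  expect_equal(a$unit, "Gy")
  expect_error(absolute_dose_map(a, 1), "already absolute")
})
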