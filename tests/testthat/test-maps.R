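test_that("flat surfaces give uniform maps at the construction height", {
  fx <- make_flat_bilayer(n_side = 4, box = c(8, 8, 10), z_head = 2,
                          n_frames = 2)
  asn <- assign_leaflets(fx$traj, fx$top)
  sm <- surface_map(fx$traj, fx$top, asn, "upper")
  expect_true(all(abs(sm$values - 7) < 1e-9))
  tm <- thickness_map(fx$traj, fx$top, asn)
  expect_true(all(abs(tm$values - 4) < 1e-9))
  # thickness mean equals difference of surface means (linearity)
  lo <- surface_map(fx$traj, fx$top, asn, "lower")
  expect_equal(mean(tm$values), mean(sm$values) - mean(lo$values),
               tolerance = 1e-12)
})

test_that("maps are equivariant under cyclic translation by one cell", {
  b <- generate_bilayer(synthetic_config(
    box = c(8, 8, 9), regions = list(region_disordered()), n_frames = 4,
    seed = 5))
  asn <- assign_leaflets(b$trajectory, b$topology)
  ref <- surface_map(b$trajectory, b$topology, asn, "upper",
                     grid_cell = 0.5, sigma = 0.5)
  shifted <- b$trajectory
  for (f in seq_along(shifted$positions)) {
    p <- shifted$positions[[f]]
    p[, 1] <- wrap_periodic(p[, 1] + 0.5, 8)
    shifted$positions[[f]] <- p
  }
  got <- surface_map(shifted, b$topology, asn, "upper",
                     grid_cell = 0.5, sigma = 0.5)
  expect_equal(got$values[c(2:16, 1), ], ref$values, tolerance = 1e-9)
})

test_that("smoothing attenuates a sinusoidal surface as expected", {
  # amplitude 0.5 nm, wavelength 12 nm, sigma 0.5 -> attenuation
  # exp(-2 pi^2 sigma^2 / lambda^2) = 0.966; recovered amplitude >= 0.45
  fx <- make_flat_bilayer(n_side = 24, box = c(12, 12, 12), n_frames = 2)
  rippled <- fx$traj
  for (f in seq_along(rippled$positions)) {
    p <- rippled$positions[[f]]
    p[, 3] <- p[, 3] + 0.5 * sin(2 * pi * p[, 1] / 12)
    rippled$positions[[f]] <- p
  }
  asn <- assign_leaflets(rippled, fx$top)
  sm <- surface_map(rippled, fx$top, asn, "upper", grid_cell = 0.5,
                    sigma = 0.5)
  amp <- (max(sm$values) - min(sm$values)) / 2
  expect_gte(amp, 0.45)
  expect_lte(amp, 0.51)
})

test_that("order maps localize chain order and flag empty cells", {
  b <- generate_bilayer(synthetic_config(
    box = c(8, 8, 9), regions = list(region_disordered(s_target = 0.3,
                                                       s_sd = 0)),
    n_frames = 4, seed = 6))
  asn <- assign_leaflets(b$trajectory, b$topology)
  pco <- per_chain_order(b$trajectory, b$topology)
  om <- order_map(pco, b$trajectory, b$topology, asn, "upper",
                  grid_cell = 1.0)
  occ <- om$counts > 0
  expect_true(all(abs(om$values[occ] - 0.3) < 1e-9))
  expect_true(all(is.nan(om$values[!occ])))
})

test_that("two-level order fields give step maps with correct plateaus", {
  b <- generate_bilayer(synthetic_config(
    box = c(16, 16, 9),
    regions = list(
      region_ordered(centre = c(8, 8), radius = 5, s_target = 0.4,
                     chol_fraction = 0, s_sd = 0.01),
      region_disordered(s_target = 0.1, s_sd = 0.01)),
    n_frames = 6, seed = 8))
  asn <- assign_leaflets(b$trajectory, b$topology)
  pco <- per_chain_order(b$trajectory, b$topology)
  om <- order_map(pco, b$trajectory, b$topology, asn, "upper",
                  grid_cell = 1.0)
  ctr <- grid_centres(om)
  d <- sqrt(outer((ctr$x - 8)^2, (ctr$y - 8)^2, "+"))
  inner <- om$values[d < 4 & om$counts > 0]
  outer_ <- om$values[d > 6 & om$counts > 0]
  expect_lt(abs(mean(inner) - 0.4), 0.02)
  expect_lt(abs(mean(outer_) - 0.1), 0.02)
})

test_that("jump maps reproduce drift, rest and random-walk statistics", {
  # all static -> all-zero
  fx <- make_flat_bilayer(n_side = 3, box = c(6, 6, 10), n_frames = 5)
  asn <- assign_leaflets(fx$traj, fx$top)
  jm0 <- jump_map(fx$traj, fx$top, asn, "upper", window = 1, grid_cell = 2)
  expect_true(all(jm0$values[jm0$counts > 0] == 0))
  # uniform drift d per window -> uniform map d
  fxd <- make_flat_bilayer(n_side = 3, box = c(6, 6, 10), n_frames = 5,
                           drift = c(0.2, 0))
  jmd <- jump_map(fxd$traj, fxd$top, asn, "upper", window = 1,
                  grid_cell = 2)
  expect_true(all(abs(jmd$values[jmd$counts > 0] - 0.2) < 1e-9))
  # 2D Gaussian random walk: mean |displacement| over k steps from a
  # direct Monte-Carlo oracle
  k <- 10L; sigma_step <- 0.05
  set.seed(12)
  oracle <- mean(sqrt(rowSums(
    matrix(stats::rnorm(2e5 * 2, 0, sigma_step * sqrt(k)), ncol = 2)^2)))
  b <- generate_bilayer(synthetic_config(
    box = c(8, 8, 9),
    regions = list(region_disordered(sigma_step = sigma_step)),
    n_frames = 41, dt = 0.1, seed = 13))
  asb <- assign_leaflets(b$trajectory, b$topology)
  jm <- jump_map(b$trajectory, b$topology, asb, "upper", window = 1,
                 grid_cell = 8)
  expect_lt(abs(jm$values[1, 1] - oracle) / oracle, 0.1)
  expect_error(jump_map(b$trajectory, b$topology, asb, "upper",
                        window = 0.01), "sampling error")
})

test_that("jump maps are invariant under time reversal", {
  b <- generate_bilayer(synthetic_config(
    box = c(8, 8, 9), regions = list(region_disordered()), n_frames = 21,
    dt = 0.1, seed = 14))
  asn <- assign_leaflets(b$trajectory, b$topology)
  fwd <- jump_map(b$trajectory, b$topology, asn, "upper", window = 2,
                  grid_cell = 8)
  rev_traj <- b$trajectory
  rev_traj$positions <- rev(rev_traj$positions)
  rev_jm <- jump_map(rev_traj, b$topology, asn, "upper", window = 2,
                     grid_cell = 8)
  expect_equal(mean(fwd$values), mean(rev_jm$values), tolerance = 0.05)
})

test_that("the interleaflet histogram is normalized and catches modes", {
  b <- generate_bilayer(fixture_config("homogeneous-lo", seed = 6))
  asn <- assign_leaflets(b$trajectory, b$topology)
  pco <- per_chain_order(b$trajectory, b$topology)
  up <- order_map(pco, b$trajectory, b$topology, asn, "upper")
  lo <- order_map(pco, b$trajectory, b$topology, asn, "lower")
  jh <- interleaflet_histogram(up, lo)
  expect_equal(sum(jh$mass), 1, tolerance = 1e-9)
  # homogeneous phase: one compact mode (spread < 2 bins around the peak)
  peak <- jh[which.max(jh$mass), ]
  w <- 2 * 0.025
  near <- abs(jh$upper - peak$upper) <= w & abs(jh$lower - peak$lower) <= w
  expect_gte(sum(jh$mass[near]), 0.85)
  bad <- up; bad$values <- bad$values[1:10, 1:10]
  expect_error(interleaflet_histogram(bad, lo), "alignment error")
})

test_that("area per lipid follows the box and the counting rule", {
  b <- generate_bilayer(synthetic_config(
    box = c(8, 8, 9), regions = list(region_disordered(chol_fraction = 0.2)),
    n_frames = 2, seed = 9))
  asn <- assign_leaflets(b$trajectory, b$topology)
  lab <- asn$labels
  n_all <- sum(lab$label == "upper")
  n_chol <- sum(lab$label == "upper" & lab$species == "CHOL")
  expect_gt(n_chol, 0)
  apl <- area_per_lipid(b$trajectory, b$topology, asn, "upper")
  expect_equal(apl, 64 / n_all, tolerance = 1e-12)
  apl_x <- area_per_lipid(b$trajectory, b$topology, asn, "upper",
                          count_sterols = FALSE)
  expect_equal(apl_x, 64 / (n_all - n_chol), tolerance = 1e-12)
  # doubling the box area doubles the value
  big <- b$trajectory; big$box[, 1] <- big$box[, 1] * 2
  expect_equal(area_per_lipid(big, b$topology, asn, "upper"), 2 * apl)
  # 18 x 18 box with 512 lipids -> 0.6328 nm^2
  expect_equal(18 * 18 / 512, 0.6328, tolerance = 1e-4)
})
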