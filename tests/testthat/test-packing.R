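# Synthetic point sets with known coordination are built directly; the
# generator-based hexagonal-core checks live in test-acceptance.R.

hex_points <- function(a = 0.49, nx = 12, ny = 12) {
  dy <- a * sqrt(3) / 2
  pts <- NULL
  for (j in seq_len(ny) - 1L)
    pts <- rbind(pts, cbind((seq_len(nx) - 1L) * a + (j %% 2L) * a / 2,
                            j * dy))
  list(xy = pts, box = c(nx * a, ny * dy))
}

test_that("lattices show their textbook coordination numbers", {
  hp <- hex_points()
  # any cutoff in (a, a sqrt 3) gives exactly 6 neighbours everywhere
  for (cut in c(0.52, 0.65, 0.82)) {
    nb <- neighbor_counts(hp$xy, hp$box, cutoff = cut)
    expect_true(all(attr(nb, "per_site") == 6L),
                label = paste("hex cutoff", round(cut, 3)))
  }
  sq <- expand.grid(x = (0:9) * 0.5, y = (0:9) * 0.5)
  nb4 <- neighbor_counts(cbind(sq$x, sq$y), c(5, 5), cutoff = 0.6)
  expect_true(all(attr(nb4, "per_site") == 4L))
  hist_tab <- tibble::as_tibble(nb4)
  expect_equal(sum(hist_tab$count), 100)
  expect_equal(hist_tab$count[hist_tab$neighbors == 4], 100)
})

test_that("the 2D RDF is flat for ideal-gas points and peaked for lattices", {
  set.seed(3)
  n <- 10000L
  xy <- cbind(stats::runif(n, 0, 20), stats::runif(n, 0, 20))
  r <- rdf_2d(xy, c(20, 20), dr = 0.05)
  far <- r$g[r$r > 1 & r$r < 8]
  expect_lt(max(abs(far - 1)), 0.05)
  hp <- hex_points(a = 0.49, nx = 20, ny = 20)
  rl <- rdf_2d(hp$xy, hp$box, dr = 0.02)
  expect_equal(attr(rl, "first_peak"), 0.49, tolerance = 0.03)
  fm <- attr(rl, "first_minimum")
  expect_gt(fm, 0.49); expect_lt(fm, 0.49 * sqrt(3))
  expect_error(rdf_2d(xy, c(20, 20), dr = 0), "config error")
})

test_that("chain sites count chains and optionally sterols", {
  b <- generate_bilayer(synthetic_config(
    box = c(6, 6, 9), regions = list(region_disordered(chol_fraction = 0.2)),
    n_frames = 2, seed = 4))
  asn <- assign_leaflets(b$trajectory, b$topology)
  lab <- asn$labels
  n_dppc <- sum(lab$label == "upper" & lab$species == "DPPC")
  n_chol <- sum(lab$label == "upper" & lab$species == "CHOL")
  s0 <- chain_sites(b$trajectory, b$topology, asn, "upper")
  s1 <- chain_sites(b$trajectory, b$topology, asn, "upper",
                    include_cholesterol = TRUE)
  expect_equal(nrow(s0), 2L * n_dppc)
  expect_equal(nrow(s1), 2L * n_dppc + n_chol)
})

test_that("neighbour counts ignore translation and site order", {
  hp <- hex_points(a = 0.5, nx = 8, ny = 8)
  ref <- sort(attr(neighbor_counts(hp$xy, hp$box, cutoff = 0.6),
                   "per_site"))
  shifted <- cbind(wrap_periodic(hp$xy[, 1] + 1.3, hp$box[1]),
                   wrap_periodic(hp$xy[, 2] + 0.7, hp$box[2]))
  expect_equal(sort(attr(neighbor_counts(shifted, hp$box, cutoff = 0.6),
                         "per_site")), ref)
  perm <- hp$xy[sample(nrow(hp$xy)), ]
  expect_equal(sort(attr(neighbor_counts(perm, hp$box, cutoff = 0.6),
                         "per_site")), ref)
  expect_warning(neighbor_counts(hp$xy, hp$box, cutoff = hp$box[1]),
                 "half the box")
})

test_that("thickness occupancy separates annulus-bound cholesterol", {
  nd <- nanodomain_fixture()
  tm <- thickness_map(nd$b$trajectory, nd$b$topology, nd$asn)
  ster <- sterol_positions(nd$b$trajectory, nd$b$topology)
  occ <- thickness_occupancy(tm, ster)
  df <- as.data.frame(occ)
  # cholesterol sits in ordered-thickness cells, none in the thick core
  expect_equal(sum(df$density_chol[df$thickness >= 4.5]), 0)
  expect_gt(sum(df$density_chol[df$thickness >= 4.0 & df$thickness < 4.4]),
            0.5)
  # cumulatives are monotone from 0 to 1
  expect_true(all(diff(df$cum_all) >= -1e-12))
  expect_true(all(diff(df$cum_chol) >= -1e-12))
  expect_equal(df$cum_all[nrow(df)], 1, tolerance = 1e-9)
  # no-sterol input is flagged
  empty <- thickness_occupancy(tm, ster[0, ])
  expect_true(attr(empty, "flagged_empty"))
})

test_that("uniformly spread cholesterol matches the all-cell curve", {
  # sterols everywhere -> the two cumulative curves coincide within the
  # two-sample KS criterion at alpha = 0.01
  b <- generate_bilayer(synthetic_config(
    box = c(12, 12, 9),
    regions = list(region_disordered(chol_fraction = 0.15)),
    n_frames = 10, seed = 19))
  asn <- assign_leaflets(b$trajectory, b$topology)
  tm <- thickness_map(b$trajectory, b$topology, asn)
  occ <- thickness_occupancy(tm, sterol_positions(b$trajectory, b$topology))
  n1 <- attr(occ, "n_all_cells"); n2 <- attr(occ, "n_chol_cells")
  crit <- 1.628 * sqrt((n1 + n2) / (n1 * n2))
  expect_lt(attr(occ, "ks_statistic"), crit)
})

test_that("collective tilt separates aligned from azimuthally random tilts", {
  fx <- make_flat_bilayer(n_side = 3, n_frames = 2)
  ct0 <- collective_tilt(fx$traj, fx$top, frames = 1)
  expect_lt(ct0$mean_angle_deg, 1e-6)
  expect_lt(ct0$direction_magnitude, 1e-6)
  # all chains tilted 30 degrees toward +x
  tilted <- fx$traj
  for (f in seq_along(tilted$positions)) {
    p <- tilted$positions[[f]]
    for (m in fx$top$molecules) {
      carb <- m$chains[[1]]$carbons
      base <- p[carb[1], ]
      for (q in seq_along(carb)) {
        step <- 0.127 * (q - 1)
        dz <- p[carb[q], 3] - base[3]
        sgn <- sign(dz + 1e-12)
        p[carb[q], ] <- base + c(step * sin(pi / 6), 0,
                                 sgn * step * cos(pi / 6))
        p[carb[q] + 1L, ] <- p[carb[q], ] + c(0, 0.109, 0)
        p[carb[q] + 2L, ] <- p[carb[q], ] +
          c(0.109 * cos(pi / 6), 0, -0.109 * sin(pi / 6))
      }
    }
    tilted$positions[[f]] <- p
  }
  ct30 <- collective_tilt(tilted, fx$top, frames = 1)
  expect_equal(ct30$mean_angle_deg, 30, tolerance = 0.5)
  expect_gt(ct30$direction_magnitude, 0.99)
  # tilted chains with uniform random azimuth: mean resultant near zero
  set.seed(77)
  az <- stats::runif(1000, 0, 2 * pi)
  resultant <- sqrt(sum(cos(az))^2 + sum(sin(az))^2) / 1000
  expect_lt(resultant, 0.1)
  b <- generate_bilayer(fixture_config("gel", seed = 4, n_frames = 4))
  ctg <- collective_tilt(b$trajectory, b$topology, frames = 2)
  expect_gt(ctg$mean_angle_deg, 10)   # beta(S = 0.42) = 19 degrees
  expect_lt(ctg$direction_magnitude, 0.1)
})

test_that("sterol face orientation detects scripted preference only", {
  cfg <- fixture_config("nanodomain-registered", seed = 3, n_frames = 6)
  cfg$face_mode <- "toward_disordered"
  b <- generate_bilayer(cfg)
  asn <- assign_leaflets(b$trajectory, b$topology)
  pco <- per_chain_order(b$trajectory, b$topology)
  om <- order_map(pco, b$trajectory, b$topology, asn, "upper", sigma = 1.0)
  fo <- glance(face_orientation_preference(b$trajectory, b$topology, om))
  expect_gt(fo$fraction, 0.95)
  expect_lt(fo$p_value, 1e-6)
  # zero-gradient map -> all sterols excluded, flagged
  flat <- om; flat$values[] <- 0.3
  fo0 <- face_orientation_preference(b$trajectory, b$topology, flat)
  expect_true(fo0$no_boundary)
})
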