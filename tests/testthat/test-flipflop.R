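test_that("leaflet traces report height relative to the local midplane", {
  b <- generate_bilayer(synthetic_config(
    box = c(8, 8, 10), regions = list(region_disordered(chol_fraction = 0.1)),
    n_frames = 4, seed = 3))
  asn <- assign_leaflets(b$trajectory, b$topology)
  chol <- nanodomains:::topology_ids(b$topology)[
    nanodomains:::topology_species(b$topology) == "CHOL"]
  tr <- leaflet_trace(b$trajectory, b$topology, chol[1], asn)
  expect_equal(nrow(tr), 4L)
  gt <- b$ground_truth$molecules
  side <- gt$leaflet[gt$molecule == chol[1]]
  expected <- if (side == "upper") 0.9 else -0.9   # thickness 1.9 - ring drop
  expect_true(all(abs(tr$height - expected) < 0.15))
})

test_that("the hysteresis detector commits only deep, dwelled crossings", {
  tr <- scripted_flip_trace(n_cross = 1, n_feints = 0)
  ev <- detect_flipflops(tr, delta = 0.4, tau_min = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "upper_to_lower")
  # oscillation confined to (-delta, delta): no events
  osc <- tibble::tibble(time = seq(0, 20, 0.1),
                        height = 0.35 * sin(seq(0, 20, 0.1)))
  expect_equal(nrow(detect_flipflops(osc, delta = 0.4, tau_min = 1)), 0L)
  expect_error(detect_flipflops(osc[1:5, ], delta = 0.4, tau_min = 10),
               "sampling error")
})

test_that("seven scripted crossings with three feints give seven events", {
  tr <- scripted_flip_trace(n_cross = 7, n_feints = 3)
  ev <- detect_flipflops(tr, delta = 0.4, tau_min = 1)
  expect_equal(nrow(ev), 7L)
  expect_equal(ev$direction,
               rep(c("upper_to_lower", "lower_to_upper"), length.out = 7))
  truth <- attr(tr, "true_events")
  expect_equal(nrow(truth), 7L)
  expect_lt(max(abs(ev$time - truth$time)), 1)
})

test_that("event counts are monotone in delta and tau_min", {
  tr <- scripted_flip_trace(n_cross = 5, n_feints = 2)
  n_by_delta <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.85),
                       function(d) nrow(detect_flipflops(tr, d, 1)), 1L)
  expect_true(all(diff(n_by_delta) <= 0))
  n_by_tau <- vapply(c(0, 0.5, 1, 2, 3, 5),
                     function(tm) nrow(detect_flipflops(tr, 0.4, tm)), 1L)
  expect_true(all(diff(n_by_tau) <= 0))
})

test_that("detection is stable under sub-threshold noise", {
  tr <- scripted_flip_trace(n_cross = 4, n_feints = 1)
  ref <- detect_flipflops(tr, delta = 0.4, tau_min = 1)
  set.seed(21)
  for (k in 1:5) {
    noisy <- tr
    noisy$height <- noisy$height + stats::runif(nrow(tr), -0.19, 0.19)
    ev <- detect_flipflops(noisy, delta = 0.4, tau_min = 1)
    expect_equal(nrow(ev), nrow(ref))
    expect_equal(ev$direction, ref$direction)
  }
})

test_that("generator-scripted flips are recovered exactly", {
  b <- generate_bilayer(fixture_config("flipflop-script", seed = 5))
  asn <- assign_leaflets(b$trajectory, b$topology)
  ev <- detect_all_flipflops(b$trajectory, b$topology, asn,
                             delta = 0.4, tau_min = 1)
  truth <- b$ground_truth$flip_events
  expect_equal(nrow(ev), nrow(truth))
  ord <- order(ev$molecule, ev$time)
  expect_equal(ev$molecule[ord], truth$molecule)
  expect_equal(ev$direction[ord], truth$direction)
  expect_lt(max(abs(ev$time[ord] - truth$time)), 1)
  # alternating-direction invariant per molecule
  for (m in unique(ev$molecule)) {
    dirs <- ev$direction[ev$molecule == m][order(ev$time[ev$molecule == m])]
    if (length(dirs) > 1)
      expect_true(all(dirs[-1] != dirs[-length(dirs)]))
  }
})

test_that("boundary enrichment finds scripted boundary events", {
  tm <- new_grid_map(
    ifelse(sqrt(outer(((1:64) - 0.5) * 0.25 - 8, rep(1, 64))^2 +
                  outer(rep(1, 64), ((1:64) - 0.5) * 0.25 - 8)^2) <= 4,
           4.6, 3.8),
    matrix(1L, 64, 64), c(16, 16), "nm")
  rm <- classify(tm, thresholds = c(4.0, 4.4))
  dmap <- nanodomains:::boundary_distance_map(rm)
  w <- 0.5
  af <- mean(dmap <= w)
  bc <- which(rm$boundary, arr.ind = TRUE)
  set.seed(6)
  pick <- bc[sample(nrow(bc), 20), ]
  ev <- tibble::tibble(molecule = sprintf("chol-%d", 1:20), time = 1,
                       direction = "upper_to_lower",
                       x = (pick[, 1] - 0.5) * 0.25,
                       y = (pick[, 2] - 0.5) * 0.25)
  enr <- flipflop_boundary_enrichment(ev, rm, shell = w)
  expect_equal(enr$event_fraction, 1)
  expect_equal(enr$ratio, 1 / enr$area_fraction, tolerance = 1e-9)
  # refined-lattice area fraction stays close to the cell-centre estimate
  expect_lt(abs(enr$area_fraction - af), 0.05)
  expect_lt(enr$p_value, 1e-3)
  expect_error(flipflop_boundary_enrichment(ev[0, ], rm, shell = w),
               "no events")
})

test_that("uniform events give unit enrichment on average", {
  tm <- new_grid_map(
    ifelse(sqrt(outer(((1:32) - 0.5) * 0.5 - 8, rep(1, 32))^2 +
                  outer(rep(1, 32), ((1:32) - 0.5) * 0.5 - 8)^2) <= 4,
           4.6, 3.8),
    matrix(1L, 32, 32), c(16, 16), "nm")
  rm <- classify(tm, thresholds = c(4.0, 4.4))
  set.seed(14)
  ratios <- replicate(200, {
    ev <- tibble::tibble(molecule = "m", time = 1, direction = "d",
                         x = stats::runif(25, 0, 16),
                         y = stats::runif(25, 0, 16))
    flipflop_boundary_enrichment(ev, rm, shell = 1.0)$ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
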