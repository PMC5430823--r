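crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("scd_bond matches the textbook geometry", {
  c0 <- c(0, 0, 0)
  expect_equal(scd_bond(c0, c(0, 0, 1.09)), 1.0)
  expect_equal(scd_bond(c0, c(1.09, 0, 0)), -0.5)
  magic <- 54.7356 * pi / 180
  expect_equal(scd_bond(c0, c(sin(magic), 0, cos(magic))), 0,
               tolerance = 1e-6)
  # invariant under hydrogen exchange and normal rescaling
  h1 <- c(0.05, 0.07, 0.02); h2 <- c(-0.03, 0.01, 0.09)
  expect_equal(scd_bond(h1, h2), scd_bond(h2, h1))
  expect_equal(scd_bond(c0, h1, c(0, 0, 1)), scd_bond(c0, h1, c(0, 0, 7)))
  expect_error(scd_bond(c0, c0), "geometry error")
  expect_error(scd_bond(c0, h1, c(0, 0, 0)), "geometry error")
})

test_that("rigid chains along z give -S_CD = 0.5 at every carbon", {
  fx <- make_flat_bilayer(n_side = 2, n_frames = 3)
  pco <- per_chain_order(fx$traj, fx$top, chain = "sn-2")
  expect_true(all(abs(pco$scd - 0.5) < 1e-12))
})

test_that("per-chain order is invariant under global rotation about z", {
  # tilted rigid chains built away from the periodic seam, so the rotated
  # copy is bond-for-bond identical up to the rotation
  set.seed(2)
  beta <- 30 * pi / 180
  frames <- lapply(1:3, function(f) {
    phi <- stats::runif(1, 0, 2 * pi)
    u <- c(sin(beta) * cos(phi), sin(beta) * sin(phi), -cos(beta))
    v1 <- c(sin(phi), -cos(phi), 0)
    v2 <- c(-cos(beta) * cos(phi), -cos(beta) * sin(phi), -sin(beta))
    carb <- t(vapply(1:3, function(k) c(6, 6, 7) + 0.13 * (k - 1) * u,
                     numeric(3)))
    rbind(c(6, 6, 8),
          carb[1, ], carb[1, ] + 0.109 * v1, carb[1, ] + 0.109 * v2,
          carb[2, ], carb[2, ] + 0.109 * v1, carb[2, ] + 0.109 * v2,
          carb[3, ], carb[3, ] + 0.109 * v1, carb[3, ] + 0.109 * v2)
  })
  top <- nanodomains:::new_topology(list(list(
    id = "dppc-1", species = "DPPC", atoms = 1:10, head = 1L,
    chains = list(
      list(label = "sn-1", carbons = c(2L, 5L, 8L),
           hydrogens = list(c(3L, 4L), c(6L, 7L), c(9L, 10L))),
      list(label = "sn-2", carbons = c(2L, 5L, 8L),
           hydrogens = list(c(3L, 4L), c(6L, 7L), c(9L, 10L)))))), 10L)
  traj <- new_trajectory(frames, 0:2, c(12, 12, 10))
  ref <- per_chain_order(traj, top)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0,
                           -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- traj
  ctr <- c(6, 6, 0)
  for (f in seq_along(rot$positions))
    rot$positions[[f]] <- sweep(sweep(rot$positions[[f]], 2, ctr) %*% R,
                                2, ctr, `+`)
  got <- per_chain_order(rot, top)
  expect_equal(got$scd, ref$scd, tolerance = 1e-10)
  # the tilt fixes the order at P2(cos beta)/2
  expect_equal(unique(round(ref$scd, 10)),
               round(0.5 * (3 * cos(beta)^2 - 1) / 2, 10))
})

test_that("isotropically tumbling chains average to zero order", {
  # single rigid rod, orientation resampled uniformly on the sphere each
  # frame; Monte-Carlo average of P2 under the uniform measure is 0
  set.seed(31)
  nf <- 10000L
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v1 <- crossprod_vec(u, a); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- crossprod_vec(u, v1)
    ph <- stats::runif(1, 0, 2 * pi)
    # two mutually perpendicular C-H directions, both normal to the chain
    # axis, rotating rigidly with the molecule
    h1 <- cos(ph) * v1 + sin(ph) * v2
    h2 <- -sin(ph) * v1 + cos(ph) * v2
    carb <- t(vapply(1:3, function(k) 3 + 0.13 * (k - 1) * u, numeric(3)))
    pos <- rbind(c(3, 3, 5),
                 carb[1, ], carb[1, ] + 0.109 * h1, carb[1, ] + 0.109 * h2,
                 carb[2, ], carb[2, ] + 0.109 * h1, carb[2, ] + 0.109 * h2,
                 carb[3, ], carb[3, ] + 0.109 * h1, carb[3, ] + 0.109 * h2)
    pos[, 1:2] <- pos[, 1:2] + 3
    frames[[f]] <- pos
  }
  top <- nanodomains:::new_topology(list(list(
    id = "dppc-1", species = "DPPC", atoms = 1:10, head = 1L,
    chains = list(
      list(label = "sn-1", carbons = c(2L, 5L, 8L),
           hydrogens = list(c(3L, 4L), c(6L, 7L), c(9L, 10L))),
      list(label = "sn-2", carbons = c(2L, 5L, 8L),
           hydrogens = list(c(3L, 4L), c(6L, 7L), c(9L, 10L)))))), 10L)
  traj <- new_trajectory(frames, (seq_len(nf) - 1) * 0.1, c(12, 12, 10))
  pco <- per_chain_order(traj, top, chain = "sn-2")
  expect_lt(max(abs(pco$scd)), 0.02)
})


test_that("distributions are normalized and resolve separated populations", {
  pco <- tibble::tibble(molecule = rep(sprintf("m%d", 1:40), each = 2),
                        chain = "sn-2",
                        carbon = rep(2:3, 40),
                        scd = rep(c(0.1, 0.4), each = 40),
                        n_frames = 1L)
  pco$scd <- rep(rep(c(0.1, 0.4), each = 2), 20)
  dist <- order_distribution(pco)
  expect_true(all(abs(rowSums(dist$mass) - 1) < 1e-12))
  for (i in seq_along(dist$carbons)) {
    occupied <- which(dist$mass[i, ] > 0)
    expect_length(occupied, 2L)
    expect_equal(unname(dist$mass[i, occupied]), c(0.5, 0.5))
  }
  # mean profile of the equal mixture sits midway (bin-centre precision)
  prof <- mean_profile(dist)
  expect_lt(max(abs(prof$scd - 0.25)), 0.006)
  # single-value population occupies one bin
  pco1 <- dplyr::mutate(pco, scd = 0.25)
  d1 <- order_distribution(pco1)
  expect_equal(max(d1$mass), 1)
  expect_lt(max(abs(mean_profile(d1)$scd - 0.25)), 0.006)
  expect_error(order_distribution(pco[0, ]), "empty")
})

test_that("mean profiles stay inside the histogram support", {
  for (phase in c("gel", "Lo", "Ld")) {
    d <- reference_distribution(phase, n_chains = 200, seed = 5)
    prof <- mean_profile(d)
    for (i in seq_along(d$carbons)) {
      occ <- range(which(d$mass[i, ] > 0))
      expect_gte(prof$scd[i], d$breaks[occ[1]])
      expect_lte(prof$scd[i], d$breaks[occ[2] + 1L])
    }
  }
})

test_that("hydrogen-free chains need explicit reconstruction", {
  fx <- make_flat_bilayer(n_side = 2, n_frames = 2)
  mols <- fx$top$molecules
  for (k in seq_along(mols))
    for (c in seq_along(mols[[k]]$chains))
      mols[[k]]$chains[[c]]$hydrogens <- list()
  top_noH <- nanodomains:::new_topology(mols, fx$top$n_atoms)
  expect_error(per_chain_order(fx$traj, top_noH), "topology error")
  pco <- per_chain_order(fx$traj, top_noH, reconstruct_hydrogens = TRUE)
  # all-trans vertical chains: reconstructed C-H perpendicular to z
  expect_true(all(abs(pco$scd - 0.5) < 1e-9))
})
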