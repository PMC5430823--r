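test_that("GRO files round-trip losslessly to format precision", {
  fx <- make_flat_bilayer(n_side = 2, n_frames = 2)
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(fx$traj, path, "gro")
  back <- read_trajectory(path, "gro")
  expect_equal(n_frames(back), 2L)
  expect_equal(back$n_atoms, fx$traj$n_atoms)
  expect_equal(back$times, fx$traj$times)
  for (f in 1:2)
    expect_lt(max(abs(back$positions[[f]] - fx$traj$positions[[f]])), 1e-3)
  expect_equal(back$box, fx$traj$box, tolerance = 1e-9)
})

test_that("XYZ files round-trip through the Angstrom side-car convention", {
  fx <- make_flat_bilayer(n_side = 2, n_frames = 3)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(fx$traj, path, "xyz")
  expect_true(file.exists(paste0(path, ".box.json")))
  back <- read_trajectory(path, "xyz")
  expect_equal(n_frames(back), 3L)
  for (f in 1:3)
    expect_lt(max(abs(back$positions[[f]] - fx$traj$positions[[f]])), 1e-6)
})

test_that("malformed and inconsistent trajectory files are rejected", {
  fx <- make_flat_bilayer(n_side = 2, n_frames = 2)
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(fx$traj, path)
  lines <- readLines(path)
  # frame 2 atom count altered -> structure error
  n_at <- fx$traj$n_atoms
  lines2 <- lines
  lines2[n_at + 5L] <- sprintf("%5d", n_at + 1L)
  p2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines2, p2)
  expect_error(read_trajectory(p2), "structure error|truncated")
  # corrupted coordinate -> parse error naming a line
  lines3 <- lines
  substr(lines3[4], 21, 28) <- "   xx.xx"
  p3 <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines3, p3)
  expect_error(read_trajectory(p3), "parse error at line 4")
  # triclinic box -> explicit unsupported-format error
  lines4 <- lines
  lines4[n_at + 3L] <- paste(lines[n_at + 3L], "0.5 0 0 0 0 0")
  p4 <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines4, p4)
  expect_error(read_trajectory(p4), "triclinic")
  expect_error(write_trajectory(list(), withr::local_tempfile()),
               "non-empty")
})

test_that("lateral displacement unwraps across the periodic boundary", {
  # one molecule drifting +0.3 nm/ns in x through the box edge
  fx <- make_flat_bilayer(n_side = 2, box = c(4, 4, 10), n_frames = 5,
                          drift = c(0.3, 0))
  for (f in seq_along(fx$traj$positions)) {
    p <- fx$traj$positions[[f]]
    p[, 1] <- nanodomains::wrap_periodic(p[, 1], 4)
    fx$traj$positions[[f]] <- p
  }
  id <- fx$top$molecules[[1]]$id
  expect_equal(lateral_displacement(fx$traj, fx$top, id, 0, 1), 0.3,
               tolerance = 1e-9)
  # across several wraps: true path displacement, not the wrapped distance
  expect_equal(lateral_displacement(fx$traj, fx$top, id, 0, 4), 1.2,
               tolerance = 1e-9)
  # static molecule
  fx2 <- make_flat_bilayer(n_side = 2, n_frames = 3)
  expect_equal(lateral_displacement(fx2$traj, fx2$top, id, 0, 2), 0)
  expect_error(lateral_displacement(fx$traj, fx$top, id, 0, 0.5),
               "sampling error")
})

test_that("trajectory invariants are enforced at construction", {
  p <- matrix(rnorm(12), 4, 3)
  expect_error(new_trajectory(list(p, p[1:3, ]), c(0, 1), c(5, 5, 5)),
               "structure error")
  expect_error(new_trajectory(list(p, p), c(0, 0), c(5, 5, 5)),
               "strictly increasing")
  expect_error(new_trajectory(list(p), 0, c(5, -1, 5)), "box")
  expect_error(new_trajectory(list(p, p, p), c(0, 1, 2.5), c(5, 5, 5)),
               "uniformly spaced")
})

test_that("leaflet labels survive global translation and x/y swap", {
  fx <- make_flat_bilayer(n_side = 3, n_frames = 2)
  ref <- assign_leaflets(fx$traj, fx$top)$labels
  shifted <- fx$traj
  for (f in seq_along(shifted$positions)) {
    p <- shifted$positions[[f]]
    p[, 1] <- nanodomains::wrap_periodic(p[, 1] + 1.7, 6)
    p[, 2] <- nanodomains::wrap_periodic(p[, 2] + 0.9, 6)
    shifted$positions[[f]] <- p
  }
  expect_equal(assign_leaflets(shifted, fx$top)$labels$label, ref$label)
  swapped <- fx$traj
  for (f in seq_along(swapped$positions))
    swapped$positions[[f]] <- swapped$positions[[f]][, c(2, 1, 3)]
  expect_equal(assign_leaflets(swapped, fx$top)$labels$label, ref$label)
})

test_that("rippled bilayers are assigned by the local midplane", {
  # sinusoidal midplane displacement, amplitude 0.8 nm
  fx <- make_flat_bilayer(n_side = 8, box = c(16, 16, 12), n_frames = 2)
  rippled <- fx$traj
  for (f in seq_along(rippled$positions)) {
    p <- rippled$positions[[f]]
    p[, 3] <- p[, 3] + 0.8 * sin(2 * pi * p[, 1] / 16)
    rippled$positions[[f]] <- p
  }
  asn <- assign_leaflets(rippled, fx$top)
  truth <- rep(c("upper", "lower"), each = 64)
  expect_equal(asn$labels$label, truth)
  # the recovered midplane tracks the ripple
  mid <- asn$midplane
  ctr <- grid_centres(mid)
  expected <- 5 + 0.15 + 0.8 * sin(2 * pi * ctr$x / 16)
  got <- rowMeans(mid$values)
  expect_gt(stats::cor(got, expected), 0.95)
})
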