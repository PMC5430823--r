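# Shared fixtures, built in code. The heavier synthetic membranes are
# generated once per session and reused across test files.

# Minimal hand-built trajectory: n flat DPPC-like molecules per leaflet.
# Each molecule: head + one 3-carbon chain with 2 H per carbon, pointing
# into the membrane. Returns list(traj, top).
make_flat_bilayer <- function(n_side = 3, box = c(6, 6, 10), z_head = 2,
                              n_frames = 2, drift = c(0, 0)) {
  spacing <- box[1] / n_side
  mols <- list(); pos0 <- NULL
  next_atom <- 1L
  k <- 0L
  for (leaflet in c(1, -1)) {
    for (i in seq_len(n_side)) for (j in seq_len(n_side)) {
      k <- k + 1L
      x <- (i - 0.5) * spacing; y <- (j - 0.5) * spacing
      head <- c(x, y, 5 + leaflet * z_head)
      carb <- lapply(1:3, function(q)
        c(x, y, 5 + leaflet * (z_head - 0.3 - 0.127 * (q - 1))))
      atoms <- list(head)
      carbons <- integer(3); hydro <- list()
      a <- next_atom  # head
      idx <- a
      for (q in 1:3) {
        cpos <- carb[[q]]
        atoms <- c(atoms, list(cpos, cpos + c(0.109, 0, 0),
                               cpos + c(0, 0.109, 0)))
        carbons[q] <- idx + 1L + (q - 1L) * 3L
        hydro[[q]] <- carbons[q] + 1:2
      }
      n_at <- 10L
      mols[[k]] <- list(id = paste0("dppc-", k), species = "DPPC",
                        atoms = next_atom:(next_atom + n_at - 1L),
                        head = next_atom,
                        chains = list(
                          list(label = "sn-1", carbons = carbons,
                               hydrogens = hydro),
                          list(label = "sn-2", carbons = carbons,
                               hydrogens = hydro)),
                        ring_atoms = integer(),
                        methyl_marker = NA_integer_)
      pos0 <- rbind(pos0, do.call(rbind, atoms))
      next_atom <- next_atom + n_at
    }
  }
  top <- nanodomains:::new_topology(mols, nrow(pos0))
  frames <- lapply(seq_len(n_frames), function(f) {
    p <- pos0
    p[, 1] <- p[, 1] + (f - 1) * drift[1]
    p[, 2] <- p[, 2] + (f - 1) * drift[2]
    p
  })
  traj <- new_trajectory(frames, (seq_len(n_frames) - 1) * 1.0, box)
  list(traj = traj, top = top)
}

# Session-cached nanodomain fixture (the heavy one used by several files).
nanodomain_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- generate_bilayer(fixture_config("nanodomain-registered",
                                           seed = 7))
      asn <- assign_leaflets(b$trajectory, b$topology)
      cache <<- list(b = b, asn = asn)
    }
    cache
  }
})

reference_set <- function() {
  list(Ld = reference_distribution("Ld", seed = 21),
       Lo = reference_distribution("Lo", seed = 22),
       gel = reference_distribution("gel", seed = 23))
}

# Independent brute-force oracle: best simplex weights by grid search.
grid_search_mixture <- function(target, refs, step = 1e-3) {
  A <- vapply(refs, function(r) as.vector(r$mass),
              numeric(length(as.vector(target$mass))))
  b <- as.vector(target$mass)
  stopifnot(ncol(A) == 2L)
  fs <- seq(0, 1, by = step)
  obj <- vapply(fs, function(f) sum((A %*% c(f, 1 - f) - b)^2), numeric(1))
  f1 <- fs[which.min(obj)]
  c(f1, 1 - f1)
}
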