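# Synthetic bilayer generator. Produces toy trajectories with the
# statistical structure the analyses consume -- region layout, target chain
# order, hexagonal core packing, cholesterol placement, interleaflet
# registration, per-region mobility, scripted flip-flops -- plus ground
# truth for every molecule. Chains are rigid rods with decorative
# hydrogens, not physical lipids: the generator targets statistics, not
# realism, and domains are placed, never evolved.
#
# Order-by-construction: a chain tilted by beta from the membrane normal
# carries two C-H unit vectors that are mutually perpendicular and both
# perpendicular to the chain axis. Over that orthonormal triple the
# P2 projections sum to zero, so the two-hydrogen mean of -S_CD equals
# P2(cos beta)/2 exactly, independent of the azimuth. Choosing
# beta = acos(sqrt((4 S + 1) / 3)) therefore realizes -S_CD = S_target
# identically at every frame for S_target in [0, 0.5]. Targets below 0
# (down to -0.125) use a two-point beta distribution (90 degrees with
# probability -4 S, magic angle otherwise).

CHAIN_CC <- 0.127   # carbon-carbon spacing along the rod, nm
CH_BOND <- 0.109    # C-H bond length, nm
STEROL_RING_DROP <- 1.0   # ring centroid sits this far below the head, nm

#' Specify one membrane region for the synthetic generator
#'
#' @param label `"core"`, `"ordered"` or `"disordered"`.
#' @param centre Disc centre (x, y) in nm, or `NULL` for the background
#'   region.
#' @param radius Disc radius, nm (`NULL` for background). May instead be a
#'   function of time (ns) returning the radius, for scripted domain
#'   shrinkage.
#' @param thickness Headgroup |z| of the leaflet in this region, nm (half
#'   the local bilayer thickness).
#' @param s_target Target chain order (-S_CD) in `[0, 0.5]`.
#' @param packing `"hexagonal"` (regular lattice) or `"jittered"`.
#' @param lattice_a Chain-site lattice constant, nm.
#' @param jitter Static site displacement s.d., nm.
#' @param chol_fraction Cholesterol mole fraction in `[0, 1]`.
#' @param sigma_step Lateral random-walk step s.d. per frame, nm.
#' @param s_sd Per-chain spread of the realized order around `s_target`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(label = c("disordered", "ordered", "core"),
                        centre = NULL, radius = NULL, thickness = 1.9,
                        s_target = 0.18,
                        packing = c("jittered", "hexagonal"),
                        lattice_a = 0.613, jitter = 0.12,
                        chol_fraction = 0, sigma_step = 0.05,
                        s_sd = 0.02) {
  label <- match.arg(label)
  packing <- match.arg(packing)
  if (s_target > 0.5) stop("config error: s_target must be <= 0.5")
  if (s_target < -0.125) stop("config error: s_target must be >= -0.125")
  if (chol_fraction < 0 || chol_fraction > 1)
    stop("config error: chol_fraction must be in [0, 1]")
  structure(list(label = label, centre = centre, radius = radius,
                 thickness = thickness, s_target = s_target,
                 packing = packing, lattice_a = lattice_a, jitter = jitter,
                 chol_fraction = chol_fraction, sigma_step = sigma_step,
                 s_sd = s_sd), class = "region_spec")
}

# Study-condition region presets. Lattice constants follow area/lipid:
# hexagonally packed core a = 0.49 nm (two chains per DPPC footprint,
# gel-like 0.42 nm^2/lipid), ordered annulus a = 0.52 (Lo-like 0.47 nm^2),
# disordered a = 0.613 (Ld-like 0.65 nm^2). Head heights give bilayer
# thicknesses 4.6 / 4.2 / 3.8 nm; cholesterol is enriched in the annulus
# and nearly absent from the core.

#' @rdname region_spec
#' @export
region_core <- function(centre, radius, ...) {
  args <- utils::modifyList(
    list(label = "core", centre = centre, radius = radius, thickness = 2.3,
         s_target = 0.42, packing = "hexagonal", lattice_a = 0.49,
         jitter = 0, chol_fraction = 0, sigma_step = 0.005,
         s_sd = 0.008), list(...))
  do.call(region_spec, args)
}

#' @rdname region_spec
#' @export
region_ordered <- function(centre, radius, ...) {
  args <- utils::modifyList(
    list(label = "ordered", centre = centre, radius = radius,
         thickness = 2.1, s_target = 0.30, packing = "jittered",
         lattice_a = 0.52, jitter = 0.05, chol_fraction = 0.25,
         sigma_step = 0.02, s_sd = 0.015), list(...))
  do.call(region_spec, args)
}

#' @rdname region_spec
#' @export
region_disordered <- function(...) {
  args <- utils::modifyList(
    list(label = "disordered", centre = NULL, radius = NULL,
         thickness = 1.9, s_target = 0.18, packing = "jittered",
         lattice_a = 0.613, jitter = 0.12, chol_fraction = 0.05,
         sigma_step = 0.05, s_sd = 0.02), list(...))
  do.call(region_spec, args)
}

#' Configuration for the synthetic bilayer generator
#'
#' @param box Box edges (Lx, Ly, Lz), nm.
#' @param regions List of [region_spec()] for the upper leaflet (exactly one
#'   background region with `centre = NULL`).
#' @param registration `"registered"` (identical layouts), `"antiregistered"`
#'   (same geometry, order/thickness scale inverted in the lower leaflet) or
#'   `"independent"` (disc centres re-drawn for the lower leaflet).
#' @param n_frames Number of frames.
#' @param dt Frame spacing, ns.
#' @param flipflops Scripted flip-flops: data frame with columns `molecule`
#'   (sterol index within the ordered sterol list, or id) and `time` (ns).
#' @param n_carbons Carbons per chain (sn numbering starts at C2).
#' @param wobble Per-frame in-plane Gaussian wobble of chain sites, nm
#'   (gives RDF peaks finite width).
#' @param head_z_sd Vertical noise of headgroup placement, nm.
#' @param face_mode Sterol rough-face orientation: `"random"` or
#'   `"toward_disordered"` (rough beta face points away from the innermost
#'   disc centre).
#' @param seed RNG seed; fully determines the output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(box = c(18, 18, 9), regions,
                             registration = c("registered",
                                              "antiregistered",
                                              "independent"),
                             n_frames = 100, dt = 0.1, flipflops = NULL,
                             n_carbons = 14, wobble = 0.02,
                             head_z_sd = 0.03,
                             face_mode = c("random", "toward_disordered"),
                             seed = 1) {
  registration <- match.arg(registration)
  face_mode <- match.arg(face_mode)
  if (length(box) != 3 || any(box <= 0)) stop("config error: bad box")
  bg <- vapply(regions, function(r) is.null(r$centre), TRUE)
  if (sum(bg) != 1L)
    stop("config error: exactly one background region (centre = NULL) ",
         "is required")
  for (r in regions[!bg]) {
    rad <- if (is.function(r$radius)) r$radius(0) else r$radius
    if (rad >= min(box[1:2]) / 2)
      stop("config error: disc of radius ", rad,
           " does not fit in the box under periodic wrapping")
  }
  structure(list(box = box, regions = regions,
                 registration = registration, n_frames = n_frames,
                 dt = dt, flipflops = flipflops, n_carbons = n_carbons,
                 wobble = wobble, head_z_sd = head_z_sd,
                 face_mode = face_mode, seed = seed),
            class = "synthetic_config")
}

region_radius <- function(r, t = 0) {
  if (is.function(r$radius)) r$radius(t) else r$radius
}

# Innermost disc containing each point (periodic), else the background.
# regions: list; returns integer region index per point.
region_of <- function(xy, regions, box, t = 0) {
  xy <- rbind(xy)
  bg <- which(vapply(regions, function(r) is.null(r$centre), TRUE))
  out <- rep(bg, nrow(xy))
  discs <- setdiff(seq_along(regions), bg)
  if (length(discs)) {
    rad <- vapply(regions[discs], region_radius, numeric(1), t = t)
    for (k in order(rad)) {
      i <- discs[k]
      d <- periodic_distance(xy, regions[[i]]$centre, box)
      out[out == bg & d <= rad[k]] <- i
    }
  }
  out
}

# Hexagonal lattice covering the box, with optional origin offset.
hex_lattice <- function(box, a, origin = c(0, 0)) {
  dy <- a * sqrt(3) / 2
  # an even row count keeps the A/B row alternation consistent across the
  # periodic wrap (an odd count would stack two like rows at the seam)
  nyr <- 2L * max(1L, round(box[2] / (2 * dy))); dy <- box[2] / nyr
  nxr <- max(1L, round(box[1] / a)); ax <- box[1] / nxr
  pts <- NULL
  for (j in seq_len(nyr) - 1L) {
    x <- (seq_len(nxr) - 1L) * ax + (j %% 2L) * ax / 2 + origin[1]
    y <- rep(j * dy + origin[2], nxr)
    pts <- rbind(pts, cbind(x, y))
  }
  cbind(wrap_periodic(pts[, 1], box[1]), wrap_periodic(pts[, 2], box[2]))
}

# Sites of one region: lattice restricted to the region with a margin of
# 0.35 a to every region boundary (keeps inter-region spacing physical).
region_sites <- function(i, regions, box) {
  r <- regions[[i]]
  origin <- if (!is.null(r$centre)) r$centre else stats::runif(2, 0, r$lattice_a)
  pts <- hex_lattice(box, r$lattice_a, origin)
  margin <- 0.35 * r$lattice_a
  keep <- region_of(pts, regions, box) == i
  for (j in seq_along(regions)) {
    rj <- regions[[j]]
    if (is.null(rj$centre)) next
    d <- periodic_distance(pts, rj$centre, box)
    rad <- region_radius(rj)
    keep <- keep & if (j == i) d <= rad - margin else
      (d <= rad - margin | d >= rad + margin)
  }
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) && r$jitter > 0)
    pts <- pts + matrix(stats::rnorm(2 * nrow(pts), 0, r$jitter), ncol = 2)
  cbind(wrap_periodic(pts[, 1], box[1]), wrap_periodic(pts[, 2], box[2]))
}

# TRUE for points inside region i that also keep `margin` clearance from
# every region boundary -- the same zone sites are placed in, so random
# walks cannot skew the data interface toward either side of a boundary.
in_region_zone <- function(xy, i, regions, box, margin) {
  xy <- rbind(xy)
  ok <- region_of(xy, regions, box) == i
  for (rj in regions) {
    if (is.null(rj$centre)) next
    d <- periodic_distance(xy, rj$centre, box)
    ok <- ok & abs(d - region_radius(rj)) >= margin
  }
  ok
}

beta_from_s <- function(s) acos(sqrt((4 * pmax(s, 0) + 1) / 3))

# Pair chain sites into DPPC molecules: row-wise consecutive pairing with a
# distance guard (so pairs never straddle an excluded disc), then greedy
# nearest-neighbour matching of the leftovers. Returns a 2-column index
# matrix; one site may stay unpaired and is silently dropped by the caller
# only when counts are odd (they are made even upstream).
pair_chain_sites <- function(sites, box, a) {
  n <- nrow(sites)
  if (n < 2L) return(matrix(integer(), ncol = 2))
  dyrow <- a * sqrt(3) / 2
  ord <- order(round(sites[, 2] / dyrow), sites[, 1])
  pairs <- NULL; pending <- NA_integer_; leftover <- integer()
  for (k in ord) {
    if (is.na(pending)) { pending <- k; next }
    if (periodic_distance(sites[pending, ], sites[k, ], box) <= 1.8 * a) {
      pairs <- rbind(pairs, c(pending, k)); pending <- NA_integer_
    } else {
      leftover <- c(leftover, pending); pending <- k
    }
  }
  if (!is.na(pending)) leftover <- c(leftover, pending)
  while (length(leftover) >= 2L) {
    i <- leftover[1]
    d <- periodic_distance(sites[leftover[-1], , drop = FALSE],
                           sites[i, ], box)
    j <- leftover[-1][which.min(d)]
    pairs <- rbind(pairs, c(i, j))
    leftover <- setdiff(leftover, c(i, j))
  }
  pairs
}

# Leaflet-specific region list under the registration mode.
leaflet_regions <- function(config, leaflet) {
  regions <- config$regions
  if (leaflet == "upper" || config$registration == "registered")
    return(regions)
  if (config$registration == "antiregistered") {
    ss <- vapply(regions, function(r) r$s_target, numeric(1))
    th <- vapply(regions, function(r) r$thickness, numeric(1))
    return(lapply(seq_along(regions), function(i) {
      r <- regions[[i]]
      r$s_target <- max(ss) + min(ss) - r$s_target
      r$thickness <- max(th) + min(th) - r$thickness
      r
    }))
  }
  # independent: re-draw disc centres
  lapply(regions, function(r) {
    if (!is.null(r$centre))
      r$centre <- stats::runif(2, 0, config$box[1:2])
    r
  })
}

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bilayer` list: `trajectory` (a
#'   `bilayer_trajectory`), `topology` (a `bilayer_topology`),
#'   `ground_truth` (list with `molecules` tibble -- id, species, leaflet,
#'   region, s_target --, `flip_events` tibble and the config), `config`.
#' @export
generate_bilayer <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_bilayer_impl(config))
}

generate_bilayer_impl <- function(config) {
  box <- config$box; nc <- config$n_carbons
  nf <- config$n_frames
  scheduled <- any(vapply(config$regions,
                          function(r) is.function(r$radius), TRUE))

  mols <- list()   # one record per molecule
  for (leaflet in c("upper", "lower")) {
    s_sign <- if (leaflet == "upper") 1 else -1
    regions <- leaflet_regions(config, leaflet)
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      sites <- region_sites(i, regions, box)
      n <- nrow(sites)
      if (!n) next
      # mole fraction x = C / (C + D) with D DPPC using two sites each:
      # C + 2D = n  =>  C = x n / (2 - x)
      xc <- r$chol_fraction
      n_chol <- round(xc * n / (2 - xc))
      if (xc > 0 && (n - n_chol) %% 2L == 1L)
        n_chol <- n_chol + if (n_chol + 1L <= n) 1L else -1L
      if (n_chol > n || (xc > 0 && n_chol == 0L))
        stop("config error: cholesterol fraction ", xc,
             " incompatible with ", n, " lattice sites in region '",
             r$label, "'")
      idx <- sample.int(n)
      chol_sites <- sites[idx[seq_len(n_chol)], , drop = FALSE]
      rest <- sites[idx[setdiff(seq_len(n), seq_len(n_chol))], ,
                    drop = FALSE]
      if (nrow(rest) %% 2L == 1L) {
        # odd leftover: drop the site nearest the region edge so no hole
        # opens in a lattice interior
        drop_k <- if (!is.null(r$centre))
          which.max(periodic_distance(rest, r$centre, box)) else 1L
        rest <- rest[-drop_k, , drop = FALSE]
      }
      pairs <- pair_chain_sites(rest, box, r$lattice_a)
      for (k in seq_len(nrow(pairs))) {
        s1 <- rest[pairs[k, 1], ]; s2 <- rest[pairs[k, 2], ]
        d12 <- c(min_image(s2[1] - s1[1], box[1]),
                 min_image(s2[2] - s1[2], box[2]))
        if (sqrt(sum(d12^2)) <= 2.5 * r$lattice_a) {
          ctr <- c(wrap_periodic(s1[1] + d12[1] / 2, box[1]),
                   wrap_periodic(s1[2] + d12[2] / 2, box[2]))
          off <- rbind(-d12 / 2, d12 / 2)
        } else {
          # stretched leftover pair (e.g. across a disc): anchor the head
          # over the first chain so it stays inside its own region
          ctr <- s1
          off <- rbind(c(0, 0), d12)
        }
        s_chain <- pmin(pmax(
          r$s_target + stats::rnorm(2, 0, r$s_sd), -0.125), 0.48)
        mols[[length(mols) + 1L]] <- list(
          species = "DPPC", leaflet = leaflet, sign = s_sign, region = i,
          regions = regions, centre = ctr,
          offsets = off, s_chain = s_chain)
      }
      for (k in seq_len(nrow(chol_sites))) {
        mols[[length(mols) + 1L]] <- list(
          species = "CHOL", leaflet = leaflet, sign = s_sign, region = i,
          regions = regions, centre = chol_sites[k, ],
          psi = stats::runif(1, 0, 2 * pi))
      }
    }
  }
  if (!length(mols)) stop("config error: no molecules generated")

  # stable ids and atom layout
  sp_count <- c(DPPC = 0L, CHOL = 0L)
  next_atom <- 1L
  top_mols <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    sp_count[m$species] <- sp_count[m$species] + 1L
    m$id <- sprintf("%s-%d", tolower(m$species), sp_count[m$species])
    if (m$species == "DPPC") {
      n_at <- 1L + 6L * nc
      at <- next_atom:(next_atom + n_at - 1L)
      head <- at[1]
      chains <- lapply(1:2, function(ci) {
        base <- at[1] + 1L + (ci - 1L) * 3L * nc
        carb <- base + 3L * (seq_len(nc) - 1L)
        list(label = c("sn-1", "sn-2")[ci], carbons = carb,
             hydrogens = lapply(seq_len(nc),
                                function(j) c(carb[j] + 1L, carb[j] + 2L)))
      })
      top_mols[[k]] <- list(id = m$id, species = "DPPC", atoms = at,
                            head = head, chains = chains,
                            ring_atoms = integer(),
                            methyl_marker = NA_integer_)
      m$atoms <- at
    } else {
      at <- next_atom:(next_atom + 5L)
      top_mols[[k]] <- list(id = m$id, species = "CHOL", atoms = at,
                            head = at[1], chains = list(),
                            ring_atoms = at[2:5], methyl_marker = at[6])
      m$atoms <- at
    }
    next_atom <- next_atom + length(m$atoms)
    mols[[k]] <- m
  }
  n_atoms <- next_atom - 1L
  top <- new_topology(top_mols, n_atoms)

  # scripted flip-flops -> per-sterol leaflet-sign schedule
  sterol_rows <- which(vapply(mols, function(m) m$species == "CHOL", TRUE))
  flip_events <- tibble::tibble(molecule = character(), time = numeric(),
                                direction = character())
  flip_sign <- matrix(rep(vapply(mols, function(m) m$sign, 1),
                          each = nf), nrow = nf)
  if (!is.null(config$flipflops) && nrow(config$flipflops)) {
    ff <- config$flipflops
    for (q in seq_len(nrow(ff))) {
      mol_key <- ff$molecule[q]
      row <- if (is.numeric(mol_key)) sterol_rows[mol_key]
             else which(vapply(mols, function(m) m$id, "") == mol_key)
      if (!length(row) || is.na(row))
        stop("config error: unknown sterol '", mol_key, "' in flip script")
      t_ev <- ff$time[q]
      fr <- which((seq_len(nf) - 1L) * config$dt >= t_ev)
      if (!length(fr)) stop("config error: flip time ", t_ev,
                            " beyond the trajectory")
      from <- flip_sign[fr[1], row]
      flip_sign[fr, row] <- -from
      flip_events <- dplyr::bind_rows(flip_events, tibble::tibble(
        molecule = mols[[row]]$id, time = t_ev,
        direction = if (from > 0) "upper_to_lower" else "lower_to_upper"))
    }
    flip_events <- dplyr::arrange(flip_events, .data$molecule, .data$time)
  }
  # smooth the sign into a ramp over 3 frames so traces cross continuously
  zeta <- flip_sign
  if (nrow(flip_events)) {
    for (j in seq_len(ncol(zeta))) {
      s <- flip_sign[, j]
      ch <- which(diff(s) != 0)
      for (c0 in ch) {
        ramp <- seq(s[c0], s[c0 + 1L], length.out = 4L)[2:3]
        upto <- min(nf, c0 + 2L)
        zeta[(c0 + 1L):upto, j] <- ramp[seq_len(upto - c0)]
      }
    }
  }

  # chain tables for vectorized rendering
  is_dppc <- vapply(mols, function(m) m$species == "DPPC", TRUE)
  dppc_rows <- which(is_dppc)
  ch_mol <- rep(dppc_rows, each = 2L)
  ch_off <- do.call(rbind, lapply(mols[dppc_rows], function(m) m$offsets))
  ch_s <- unlist(lapply(mols[dppc_rows], function(m) m$s_chain))
  ch_sign <- vapply(mols[ch_mol], function(m) m$sign, 1)
  ch_carb <- do.call(rbind, lapply(dppc_rows, function(k) {
    rbind(top_mols[[k]]$chains[[1]]$carbons, top_mols[[k]]$chains[[2]]$carbons)
  }))
  n_chain <- length(ch_s)

  mol_centre <- do.call(rbind, lapply(mols, function(m) m$centre))
  mol_region <- vapply(mols, function(m) m$region, 1L)
  mol_sigma <- vapply(mols, function(m)
    m$regions[[m$region]]$sigma_step, numeric(1))
  n_mol <- length(mols)

  # per-frame molecule walk with in-region rejection
  walks <- array(0, c(nf, n_mol, 2))
  pos_now <- mol_centre
  for (f in seq_len(nf)) {
    if (f > 1L) {
      step <- matrix(stats::rnorm(2 * n_mol, 0, 1), ncol = 2) * mol_sigma
      prop <- pos_now + step
      prop[, 1] <- wrap_periodic(prop[, 1], box[1])
      prop[, 2] <- wrap_periodic(prop[, 2], box[2])
      if (!scheduled) {
        ok <- vapply(seq_len(n_mol), function(k) {
          m <- mols[[k]]
          in_region_zone(prop[k, ], m$region, m$regions, box,
                         0.35 * m$regions[[m$region]]$lattice_a)
        }, TRUE)
        prop[!ok, ] <- pos_now[!ok, ]
      }
      pos_now <- prop
    }
    walks[f, , ] <- pos_now
  }

  positions <- vector("list", nf)
  times <- (seq_len(nf) - 1L) * config$dt
  for (f in seq_len(nf)) {
    t_now <- times[f]
    P <- matrix(NA_real_, n_atoms, 3)
    mol_xy <- walks[f, , , drop = TRUE]
    if (n_mol == 1L) mol_xy <- matrix(mol_xy, ncol = 2)

    # effective region per molecule (handles scheduled shrinkage)
    eff_region <- mol_region
    if (scheduled) {
      up_rows <- vapply(mols, function(m) m$leaflet == "upper", TRUE)
      eff_region[up_rows] <- region_of(mol_xy[up_rows, , drop = FALSE],
                                       leaflet_regions(config, "upper"),
                                       box, t = t_now)
      eff_region[!up_rows] <- region_of(mol_xy[!up_rows, , drop = FALSE],
                                        leaflet_regions(config, "lower"),
                                        box, t = t_now)
    }
    reg_of_mol <- function(k) mols[[k]]$regions[[eff_region[k]]]
    mol_th <- vapply(seq_len(n_mol), function(k) reg_of_mol(k)$thickness,
                     numeric(1))

    # chains ---------------------------------------------------------
    eff_s <- ch_s
    if (scheduled) {
      moved <- eff_region[ch_mol] != mol_region[ch_mol]
      if (any(moved))
        eff_s[moved] <- vapply(which(moved), function(q)
          reg_of_mol(ch_mol[q])$s_target, numeric(1))
    }
    beta <- beta_from_s(eff_s)
    neg <- eff_s < 0
    if (any(neg)) {
      flat <- stats::runif(sum(neg)) < -4 * eff_s[neg]
      beta[neg] <- ifelse(flat, pi / 2, acos(sqrt(1 / 3)))
    }
    phi <- stats::runif(n_chain, 0, 2 * pi)
    sb <- sin(beta); cb <- cos(beta)
    az <- -ch_sign * cb
    ax <- sb * cos(phi); ay <- sb * sin(phi)
    # the rod is tilted, so shift its top carbon by half the lateral
    # extent: the chain-carbon centroid then sits exactly on the site
    half_ext <- (nc - 1L) / 2 * CHAIN_CC
    cx <- mol_xy[ch_mol, 1] + ch_off[, 1] - half_ext * ax +
      stats::rnorm(n_chain, 0, config$wobble)
    cy <- mol_xy[ch_mol, 2] + ch_off[, 2] - half_ext * ay +
      stats::rnorm(n_chain, 0, config$wobble)
    z_top <- ch_sign * (mol_th[ch_mol] - 0.3)
    u1 <- cbind(sin(phi), -cos(phi), 0)
    u2 <- cbind(az * cos(phi), az * sin(phi), -sb)
    for (k in seq_len(nc)) {
      step <- (k - 1L) * CHAIN_CC
      cpos <- cbind(cx + step * ax, cy + step * ay, z_top + step * az)
      ai <- ch_carb[, k]
      P[ai, ] <- cpos
      P[ai + 1L, ] <- cpos + CH_BOND * u1
      P[ai + 2L, ] <- cpos + CH_BOND * u2
    }
    # heads
    for (k in dppc_rows) {
      P[top_mols[[k]]$head, ] <-
        c(mol_xy[k, ], mols[[k]]$sign * mol_th[k] +
            stats::rnorm(1, 0, config$head_z_sd))
    }
    # sterols --------------------------------------------------------
    for (k in sterol_rows) {
      m <- mols[[k]]
      zk <- zeta[f, k]
      th <- mol_th[k]
      ctr <- c(mol_xy[k, ], zk * (th - STEROL_RING_DROP))
      psi <- if (config$face_mode == "toward_disordered") {
        reg <- m$regions
        discs <- which(!vapply(reg, function(r) is.null(r$centre), TRUE))
        if (length(discs)) {
          dc <- reg[[discs[which.min(vapply(reg[discs], region_radius,
                                            numeric(1)))]]]$centre
          dv <- c(min_image(mol_xy[k, 1] - dc[1], box[1]),
                  min_image(mol_xy[k, 2] - dc[2], box[2]))
          if (sum(dv^2) < 1e-12) dv <- c(1, 0)
          w <- dv / sqrt(sum(dv^2))
          atan2(-w[1], w[2])
        } else m$psi
      } else m$psi
      v <- c(cos(psi), sin(psi), 0)
      w <- c(-sin(psi), cos(psi), 0)
      at <- m$atoms
      P[at[1], ] <- c(ctr[1:2], zk * th * 0.95)         # hydroxyl O
      P[at[2], ] <- ctr + 0.22 * v + c(0, 0, 0.25)
      P[at[3], ] <- ctr + 0.22 * v - c(0, 0, 0.25)
      P[at[4], ] <- ctr - 0.22 * v + c(0, 0, 0.25)
      P[at[5], ] <- ctr - 0.22 * v - c(0, 0, 0.25)
      P[at[6], ] <- ctr + 0.15 * w                      # beta-face marker
    }
    P[, 1] <- wrap_periodic(P[, 1], box[1])
    P[, 2] <- wrap_periodic(P[, 2], box[2])
    P[, 3] <- P[, 3] + box[3] / 2   # centre the bilayer in the box
    positions[[f]] <- P
  }

  traj <- new_trajectory(positions, times, box)
  gt_mols <- tibble::tibble(
    molecule = vapply(mols, function(m) m$id, ""),
    species = vapply(mols, function(m) m$species, ""),
    leaflet = vapply(mols, function(m) m$leaflet, ""),
    region = vapply(mols, function(m) m$regions[[m$region]]$label, ""),
    s_target = vapply(mols, function(m)
      m$regions[[m$region]]$s_target, numeric(1)))
  structure(list(trajectory = traj, topology = top,
                 ground_truth = list(molecules = gt_mols,
                                     flip_events = flip_events),
                 config = config),
            class = "synthetic_bilayer")
}

#' @export
print.synthetic_bilayer <- function(x, ...) {
  cat("<synthetic_bilayer> ")
  print(x$trajectory)
  invisible(x)
}

#' Parametric reference order distributions for homogeneous phases
#'
#' Stand-ins for homogeneous reference systems: per-carbon -S_CD
#' distributions with documented means and widths (gel: high and narrow,
#' Lo: intermediate, Ld: low and broad), built by sampling per-chain
#' time-averaged values (a chain-level offset shared along the chain plus
#' small per-carbon noise) and histogramming per carbon.
#'
#' @param phase `"gel"`, `"Lo"` or `"Ld"`.
#' @param carbons Carbon index list (sn-2 numbering).
#' @param n_chains Number of chains sampled (>= 1).
#' @param seed RNG seed.
#' @param breaks Histogram bin edges.
#' @return An `order_distribution`.
#' @export
reference_distribution <- function(phase = c("gel", "Lo", "Ld"),
                                   carbons = 2:15, n_chains = 2000,
                                   seed = 1,
                                   breaks = default_order_breaks()) {
  if (!phase[1] %in% c("gel", "Lo", "Ld"))
    stop("unknown phase label '", phase[1], "' (use gel, Lo or Ld)")
  phase <- match.arg(phase)
  if (n_chains < 1) stop("n_chains must be >= 1")
  par <- switch(phase,
    gel = list(mu = function(c) 0.43 - 0.004 * pmax(0, c - 10), sd = 0.012),
    Lo = list(mu = function(c) 0.34 - 0.012 * pmax(0, c - 9), sd = 0.030),
    Ld = list(mu = function(c) 0.21 - 0.015 * pmax(0, c - 8), sd = 0.050))
  withr::with_seed(seed, {
    mu <- par$mu(carbons)
    off <- stats::rnorm(n_chains, 0, par$sd)
    nb <- length(breaks) - 1L
    mass <- matrix(0, length(carbons), nb)
    for (i in seq_along(carbons)) {
      v <- mu[i] + off + stats::rnorm(n_chains, 0, par$sd / 3)
      v <- pmin(pmax(v, breaks[1]), breaks[length(breaks)] - 1e-12)
      tb <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = nb)
      mass[i, ] <- tb / sum(tb)
    }
    new_order_distribution(carbons, breaks, mass,
                           provenance = paste0("reference:", phase))
  })
}

#' Scripted leaflet-height trace for flip-flop detector tests
#'
#' Builds a height trace (sterol ring-centroid height relative to the local
#' midplane) with `n_cross` committed crossings and `n_feints` shallow
#' excursions that stay within the hysteresis band.
#'
#' @param n_cross Number of committed crossings.
#' @param n_feints Number of sub-threshold feints interleaved between them.
#' @param amp Resting |height|, nm.
#' @param feint_depth How far a feint reaches past the midplane, nm (must
#'   stay below the detector threshold delta).
#' @param dt Frame spacing, ns.
#' @param plateau Frames spent at rest between excursions.
#' @param ramp Frames spent crossing.
#' @return Tibble `frame`, `time`, `height` with attribute `true_events`
#'   (tibble `time`, `direction`).
#' @export
scripted_flip_trace <- function(n_cross = 7, n_feints = 3, amp = 0.8,
                                feint_depth = 0.3, dt = 0.1, plateau = 25,
                                ramp = 5) {
  h <- rep(amp, plateau)
  events <- list()
  side <- 1
  feint_slots <- if (n_feints > 0 && n_cross > 1)
    unique(round(seq(1, n_cross - 1, length.out = n_feints))) else integer()
  for (k in seq_len(n_cross)) {
    t_cross <- (length(h) + ramp / 2) * dt
    h <- c(h, seq(side * amp, -side * amp, length.out = ramp + 2L)[-1],
           rep(-side * amp, plateau))
    events[[k]] <- tibble::tibble(
      time = t_cross,
      direction = if (side > 0) "upper_to_lower" else "lower_to_upper")
    side <- -side
    if (k %in% feint_slots) {
      # shallow excursion: crosses the midplane but stays inside (-delta, delta)
      dip <- seq(side * amp, -side * feint_depth, length.out = ramp + 1L)
      h <- c(h, dip[-1], rev(dip)[-1], rep(side * amp, plateau))
    }
  }
  tibble::tibble(frame = seq_along(h), time = (seq_along(h) - 1L) * dt,
                 height = h) |>
    structure(true_events = dplyr::bind_rows(events))
}
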