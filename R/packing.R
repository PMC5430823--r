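# Nearest-neighbour statistics and hexagonal-packing detection; cholesterol
# partitioning versus local thickness; collective chain tilt; sterol
# face-orientation preference at the domain boundary.

#' Chain sites of one leaflet in one frame
#'
#' One 2D site per DPPC acyl chain (chain-carbon centroid projected onto
#' the membrane plane); with `include_cholesterol = TRUE`, one extra site
#' per sterol (ring-centroid projection) -- the paper-style "cholesterol as
#' a lipid chain" variant.
#'
#' @param traj,top,assignment As elsewhere.
#' @param leaflet `"upper"` or `"lower"`.
#' @param include_cholesterol Add sterol sites?
#' @param frame Frame index.
#' @return Tibble `molecule`, `chain` (`"sterol"` for sterols), `x`, `y`.
#' @export
chain_sites <- function(traj, top, assignment,
                        leaflet = c("upper", "lower"),
                        include_cholesterol = FALSE, frame = 1L) {
  leaflet <- match.arg(leaflet)
  pos <- traj$positions[[frame]]; box <- traj$box[frame, ]
  lab <- assignment$labels
  rows <- list()
  for (m in top$molecules) {
    ml <- lab$label[match(m$id, lab$molecule)]
    if (is.na(ml) || ml != leaflet) next
    if (m$species == "DPPC") {
      for (ch in m$chains) {
        c2 <- periodic_centroid(pos[ch$carbons, , drop = FALSE], box)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          molecule = m$id, chain = ch$label,
          x = wrap_periodic(c2[1], box[1]),
          y = wrap_periodic(c2[2], box[2]))
      }
    } else if (include_cholesterol && is_sterol(m$species)) {
      c2 <- periodic_centroid(pos[m$ring_atoms, , drop = FALSE], box)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        molecule = m$id, chain = "sterol",
        x = wrap_periodic(c2[1], box[1]),
        y = wrap_periodic(c2[2], box[2]))
    }
  }
  if (!length(rows)) return(tibble::tibble(molecule = character(),
                                           chain = character(),
                                           x = numeric(), y = numeric()))
  dplyr::bind_rows(rows)
}

#' Periodic 2D radial distribution function
#'
#' @param sites Data frame with `x`, `y` columns (or an n x 2 matrix), nm.
#' @param box Length-2 box edges, nm.
#' @param dr Radial bin width, nm.
#' @param r_max Maximum radius (default: half the shorter box edge).
#' @return Tibble `r` (bin centre), `g`, with attributes `first_peak` and
#'   `first_minimum` (nm) -- the standard self-calibrating neighbour cutoff.
#' @export
rdf_2d <- function(sites, box, dr = 0.02, r_max = NULL) {
  if (dr <= 0) stop("config error: dr must be > 0")
  xy <- if (is.matrix(sites)) sites else cbind(sites$x, sites$y)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 sites")
  r_max <- r_max %||% (min(box[1:2]) / 2)
  d <- pairwise_periodic_dist(xy, box)
  d <- d[upper.tri(d)]
  d <- d[d < r_max]
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                     nbins = nb)
  rho <- n / prod(box[1:2])
  rc <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  g <- 2 * counts / (n * rho * shell)
  out <- tibble::tibble(r = rc, g = g)
  mins <- rdf_landmarks(rc, g)
  structure(out, first_peak = mins$peak, first_minimum = mins$minimum,
            class = c("rdf_2d", class(out)))
}

# First peak and the first minimum after it, on a lightly smoothed g(r).
rdf_landmarks <- function(r, g) {
  k <- 5L
  gs <- stats::filter(g, rep(1 / k, k), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  gs <- as.numeric(gs)
  n <- length(gs)
  peak <- NA_integer_
  for (i in 2:(n - 1L)) {
    if (gs[i] >= gs[i - 1L] && gs[i] >= gs[i + 1L] && gs[i] > 1.2) {
      peak <- i; break
    }
  }
  if (is.na(peak)) return(list(peak = NA_real_, minimum = NA_real_))
  # smoothing flattens sharp peaks into plateaus; refine to the raw argmax
  # within the smoothing window
  win <- max(1L, peak - k):min(n, peak + k)
  peak <- win[which.max(g[win])]
  minimum <- NA_integer_
  for (i in (peak + 1L):(n - 1L)) {
    if (gs[i] <= gs[i - 1L] && gs[i] <= gs[i + 1L] && gs[i] < gs[peak]) {
      minimum <- i; break
    }
  }
  if (is.na(minimum)) minimum <- peak + which.min(gs[(peak + 1L):n])
  list(peak = r[peak], minimum = r[minimum])
}

#' Neighbour-count histogram of chain sites
#'
#' Counts, per site, the other sites within `cutoff` under the periodic
#' minimum image. A mode at six neighbours diagnoses hexagonal packing.
#'
#' @param sites As in [rdf_2d()].
#' @param box Length-2 box edges, nm.
#' @param cutoff Neighbour cutoff, nm; default: first RDF minimum computed
#'   from the sites themselves.
#' @return A `neighbor_histogram` tibble (`neighbors`, `count`) with
#'   attributes `per_site` (integer vector), `cutoff`.
#' @export
neighbor_counts <- function(sites, box, cutoff = NULL) {
  xy <- if (is.matrix(sites)) sites else cbind(sites$x, sites$y)
  if (is.null(cutoff)) {
    cutoff <- attr(rdf_2d(sites, box), "first_minimum")
    if (!is.finite(cutoff))
      stop("could not locate an RDF minimum; supply a cutoff")
  }
  if (cutoff <= 0) stop("config error: cutoff must be > 0")
  if (cutoff > min(box[1:2]) / 2)
    warning("cutoff exceeds half the box; minimum image still applied ",
            "per axis")
  d <- pairwise_periodic_dist(xy, box)
  diag(d) <- Inf
  per_site <- as.integer(rowSums(d <= cutoff))
  counts <- tabulate(per_site + 1L, nbins = max(13L, max(per_site) + 1L))
  out <- tibble::tibble(neighbors = seq_along(counts) - 1L, count = counts)
  structure(out, per_site = per_site, cutoff = cutoff,
            class = c("neighbor_histogram", class(out)))
}

#' Thickness occupancy of cholesterol
#'
#' Compares the distribution of local membrane thickness over all grid
#' cells with the distribution over cells occupied by at least one sterol
#' reference point (accumulated over frames), both as normalized histograms
#' and normalized cumulative curves. Cholesterol enriched in thick ordered
#' regions but excluded from the thickest (hexagonal) core shows up as a
#' cumulative curve that leads the all-cell curve at intermediate
#' thicknesses and has no mass in the top bins.
#'
#' @param thickness A thickness `grid_map`.
#' @param sterol_xy Tibble with `frame`, `x`, `y` of sterol reference
#'   points over time (nm), e.g. from [sterol_positions()].
#' @param breaks Thickness bin edges, nm (default 0.05-nm bins spanning the
#'   map).
#' @return A `thickness_occupancy` tibble (`thickness`, `density_all`,
#'   `density_chol`, `cum_all`, `cum_chol`) with attributes `n_chol_cells`,
#'   `ks_statistic`, `flagged_empty`.
#' @export
thickness_occupancy <- function(thickness, sterol_xy, breaks = NULL) {
  v <- thickness$values
  ok <- is.finite(v)
  if (is.null(breaks)) {
    rng <- range(v[ok])
    breaks <- seq(floor(rng[1] * 20) / 20, ceiling(rng[2] * 20) / 20,
                  by = 0.05)
  }
  nb <- length(breaks) - 1L
  clamp <- function(x) pmin(pmax(x, breaks[1]), breaks[nb + 1L] - 1e-12)
  all_counts <- tabulate(findInterval(clamp(v[ok]), breaks,
                                      rightmost.closed = TRUE), nbins = nb)
  chol_vals <- numeric()
  if (nrow(sterol_xy)) {
    nx <- nrow(v); ny <- ncol(v)
    for (f in unique(sterol_xy$frame)) {
      sf <- sterol_xy[sterol_xy$frame == f, , drop = FALSE]
      ij <- grid_cell_index(cbind(sf$x, sf$y), thickness$box, nx, ny)
      occ <- unique(ij[, 1] + nx * (ij[, 2] - 1L))
      vv <- v[occ]
      chol_vals <- c(chol_vals, vv[is.finite(vv)])
    }
  }
  flagged <- length(chol_vals) == 0L
  chol_counts <- if (flagged) rep(0L, nb) else
    tabulate(findInterval(clamp(chol_vals), breaks,
                          rightmost.closed = TRUE), nbins = nb)
  da <- all_counts / sum(all_counts)
  dc <- if (flagged) rep(NA_real_, nb) else chol_counts / sum(chol_counts)
  ca <- cumsum(da)
  cc <- if (flagged) rep(NA_real_, nb) else cumsum(dc)
  out <- tibble::tibble(
    thickness = (breaks[-1] + breaks[-length(breaks)]) / 2,
    density_all = da, density_chol = dc, cum_all = ca, cum_chol = cc)
  ks <- if (flagged) NA_real_ else max(abs(ca - cc))
  structure(out, n_chol_cells = length(chol_vals), ks_statistic = ks,
            n_all_cells = sum(ok), flagged_empty = flagged,
            breaks = breaks,
            class = c("thickness_occupancy", class(out)))
}

#' Sterol reference positions over time
#'
#' @param traj,top As elsewhere.
#' @param frames Frame indices (default all).
#' @return Tibble `molecule`, `frame`, `time`, `x`, `y` of ring-centroid
#'   projections.
#' @export
sterol_positions <- function(traj, top, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  sterols <- Filter(function(m) is_sterol(m$species), top$molecules)
  if (!length(sterols)) return(tibble::tibble(
    molecule = character(), frame = integer(), time = numeric(),
    x = numeric(), y = numeric()))
  purrr::map_dfr(frames, function(f) {
    pos <- traj$positions[[f]]; box <- traj$box[f, ]
    ct <- t(vapply(sterols, function(m)
      periodic_centroid(pos[m$ring_atoms, , drop = FALSE], box), numeric(3)))
    tibble::tibble(molecule = vapply(sterols, function(m) m$id, ""),
                   frame = f, time = traj$times[f],
                   x = wrap_periodic(ct[, 1], box[1]),
                   y = wrap_periodic(ct[, 2], box[2]))
  })
}

#' Collective tilt of lipid chains in a region
#'
#' Chain axes are taken as the first principal component of the chain
#' carbons (robust to gauche defects), oriented to point into the
#' membrane. Reports the mean tilt angle from the membrane normal and the
#' mean resultant of the unit in-plane tilt directions: |direction| near 0
#' means tilts are azimuthally uncorrelated (no collective tilt), near 1
#' means a common tilt direction.
#'
#' @param traj,top As elsewhere.
#' @param molecules Molecule ids to include (default: all DPPC).
#' @param frames Frame indices (default: first frame).
#' @return List with `mean_angle_deg`, `direction` (length-2),
#'   `direction_magnitude` in `[0, 1]`, `n_chains`.
#' @export
collective_tilt <- function(traj, top, molecules = NULL, frames = 1L) {
  mols <- Filter(function(m) m$species == "DPPC" &&
                   (is.null(molecules) || m$id %in% molecules),
                 top$molecules)
  if (!length(mols)) stop("region with no chains")
  angs <- numeric(); dirs <- NULL
  for (f in frames) {
    pos <- traj$positions[[f]]; box <- traj$box[f, ]
    for (m in mols) {
      for (ch in m$chains) {
        pc <- pos[ch$carbons, , drop = FALSE]
        ref <- pc[1, ]
        for (j in 1:3) pc[, j] <- ref[j] + min_image(pc[, j] - ref[j], box[j])
        a <- svd(scale(pc, scale = FALSE), nu = 0, nv = 1)$v[, 1]
        # orient into the membrane: top carbon is listed first
        if (sum(a * (pc[nrow(pc), ] - pc[1, ])) < 0) a <- -a
        angs <- c(angs, acos(pmin(1, abs(a[3]))) * 180 / pi)
        axy <- a[1:2]
        nxy <- sqrt(sum(axy^2))
        dirs <- rbind(dirs, if (nxy > 1e-9) axy / nxy else c(0, 0))
      }
    }
  }
  mean_dir <- colMeans(dirs)
  list(mean_angle_deg = mean(angs), direction = mean_dir,
       direction_magnitude = sqrt(sum(mean_dir^2)), n_chains = length(angs))
}

#' Sterol face-orientation preference at order gradients
#'
#' For every sterol and frame, the rough (beta, methyl-bearing) face
#' direction is the in-plane unit vector from the ring centroid to the
#' methyl marker; the local "ordered side" direction is the gradient of
#' the order map at the sterol position. Sterols sitting where the
#' gradient is negligible (no boundary) are excluded. Reports the
#' distribution of the angle between the two and a binomial test of
#' "rough face toward the disordered side" against chance (0.5).
#'
#' @param traj,top As elsewhere.
#' @param order_map A local-order `grid_map` (smoothed maps work best).
#' @param min_gradient Exclusion threshold on |gradient| (-S_CD per nm).
#' @param frames Frame indices (default all).
#' @return A `face_orientation` object with [tidy()] (per-observation
#'   angles) and [glance()] (n, fraction, p-value, `no_boundary` flag).
#' @export
face_orientation_preference <- function(traj, top, order_map,
                                        min_gradient = 0.02,
                                        frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  sterols <- Filter(function(m) is_sterol(m$species), top$molecules)
  if (!length(sterols)) stop("no sterols in the topology")
  for (m in sterols) if (is.na(m$methyl_marker))
    stop("topology error: sterol '", m$id, "' lacks a methyl-marker atom")
  gr <- grid_gradient(order_map)
  nx <- nrow(order_map$values); ny <- ncol(order_map$values)
  rows <- list()
  for (f in frames) {
    pos <- traj$positions[[f]]; box <- traj$box[f, ]
    for (m in sterols) {
      ct <- periodic_centroid(pos[m$ring_atoms, , drop = FALSE], box)
      w <- pos[m$methyl_marker, 1:2] - ct[1:2]
      w <- c(min_image(w[1], box[1]), min_image(w[2], box[2]))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-9) next
      w <- w / nw
      ij <- grid_cell_index(rbind(ct[1:2]), order_map$box, nx, ny)
      g <- c(gr$gx[ij[1], ij[2]], gr$gy[ij[1], ij[2]])
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn < min_gradient) next
      cosang <- sum(w * g) / gn
      rows[[length(rows) + 1L]] <- tibble::tibble(
        molecule = m$id, frame = f,
        angle_deg = acos(pmin(1, pmax(-1, cosang))) * 180 / pi,
        toward_disordered = cosang < 0)
    }
  }
  obs <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(molecule = character(), frame = integer(),
                   angle_deg = numeric(), toward_disordered = logical())
  no_boundary <- nrow(obs) == 0L
  test <- if (!no_boundary)
    stats::binom.test(sum(obs$toward_disordered), nrow(obs), 0.5) else NULL
  structure(list(observations = obs, no_boundary = no_boundary,
                 fraction = if (no_boundary) NA_real_
                            else mean(obs$toward_disordered),
                 p_value = if (no_boundary) NA_real_ else test$p.value),
            class = "face_orientation")
}

# Periodic central-difference gradient of a grid map (NaN-tolerant:
# gradients touching empty cells are NaN).
grid_gradient <- function(map) {
  v <- map$values
  nx <- nrow(v); ny <- ncol(v)
  xp <- v[c(2:nx, 1), , drop = FALSE]; xm <- v[c(nx, 1:(nx - 1)), , drop = FALSE]
  yp <- v[, c(2:ny, 1), drop = FALSE]; ym <- v[, c(ny, 1:(ny - 1)), drop = FALSE]
  list(gx = (xp - xm) / (2 * map$cell[1]), gy = (yp - ym) / (2 * map$cell[2]))
}

#' @export
print.face_orientation <- function(x, ...) {
  if (x$no_boundary)
    cat("<face_orientation> no boundary: all sterols excluded",
        "(order gradient below threshold)\n")
  else
    cat("<face_orientation> n =", nrow(x$observations),
        sprintf("rough-face-toward-disordered fraction = %.3f, p = %.3g\n",
                x$fraction, x$p_value))
  invisible(x)
}

#' @export
tidy.face_orientation <- function(x, ...) x$observations

#' @export
glance.face_orientation <- function(x, ...) {
  tibble::tibble(n = nrow(x$observations), fraction = x$fraction,
                 p_value = x$p_value, no_boundary = x$no_boundary)
}
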