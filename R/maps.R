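# Periodic gridded maps over the membrane plane: headgroup surfaces,
# thickness, local chain order, and jump (displacement) maps, plus the
# interleaflet order-correlation joint histogram.
#
# Grid convention: Nx = round(Lx / cell) cells per axis (at least 1), with
# the actual cell edge Lx/Nx so the grid tiles the box exactly; cell (i, j)
# covers [(i-1)*cx, i*cx) x [(j-1)*cy, j*cy), centres at ((i-1/2)*cx, ...).

#' Construct a periodic grid map
#'
#' @param values Nx x Ny numeric matrix (NaN/NA allowed in empty cells).
#' @param counts Nx x Ny occupancy counts (>= 0).
#' @param box Length-2 box edges (Lx, Ly), nm.
#' @param unit Unit label for the values.
#' @return A `grid_map` object.
#' @export
new_grid_map <- function(values, counts = NULL, box, unit = "") {
  if (is.null(counts)) counts <- matrix(1L, nrow(values), ncol(values))
  stopifnot(is.matrix(values), all(dim(values) == dim(counts)),
            length(box) >= 2, all(box[1:2] > 0), all(counts >= 0))
  if (any(counts > 0 & !is.finite(values)))
    stop("non-finite values are only allowed in zero-occupancy cells")
  structure(list(values = values, counts = counts, box = box[1:2],
                 cell = c(box[1] / nrow(values), box[2] / ncol(values)),
                 unit = unit, periodic = TRUE),
            class = "grid_map")
}

grid_dims <- function(box, cell) {
  c(max(1L, round(box[1] / cell)), max(1L, round(box[2] / cell)))
}

# Cell indices (i, j) for points xy (wrapped first).
grid_cell_index <- function(xy, box, nx, ny) {
  i <- pmin(nx, 1L + floor(wrap_periodic(xy[, 1], box[1]) / (box[1] / nx)))
  j <- pmin(ny, 1L + floor(wrap_periodic(xy[, 2], box[2]) / (box[2] / ny)))
  cbind(as.integer(i), as.integer(j))
}

# Accumulate weighted values onto a grid; returns sums and counts matrices.
grid_accumulate <- function(xy, w, box, nx, ny) {
  ij <- grid_cell_index(xy, box, nx, ny)
  lin <- ij[, 1] + nx * (ij[, 2] - 1L)
  sums <- matrix(0, nx, ny); cnts <- matrix(0L, nx, ny)
  tw <- tapply(w, lin, sum); tc <- tapply(rep(1L, length(lin)), lin, sum)
  sums[as.integer(names(tw))] <- tw
  cnts[as.integer(names(tc))] <- tc
  list(sums = sums, counts = cnts)
}

#' Grid-cell centre coordinates
#' @param map A `grid_map`.
#' @return List with vectors `x`, `y` of cell centres, nm.
#' @export
grid_centres <- function(map) {
  list(x = (seq_len(nrow(map$values)) - 0.5) * map$cell[1],
       y = (seq_len(ncol(map$values)) - 0.5) * map$cell[2])
}

#' @export
print.grid_map <- function(x, ...) {
  cat("<grid_map> ", nrow(x$values), " x ", ncol(x$values), " cells (",
      sprintf("%.3f x %.3f", x$cell[1], x$cell[2]), " nm), unit '",
      x$unit, "', ", sum(!is.finite(x$values)), " empty cells\n", sep = "")
  invisible(x)
}

#' Tidy view of a grid map
#' @param x A `grid_map`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (cell centres, nm), `value`, `n`.
#' @export
as_tibble.grid_map <- function(x, ...) {
  ctr <- grid_centres(x)
  tibble::tibble(x = rep(ctr$x, times = length(ctr$y)),
                 y = rep(ctr$y, each = length(ctr$x)),
                 value = as.vector(x$values),
                 n = as.vector(x$counts))
}

# Periodic Gaussian smoothing of gridded observations. Works on the
# (sum, count) representation: smoothed value = K*(sums) / K*(counts), i.e.
# a kernel-weighted mean of all observations, which fills empty cells
# naturally. Cells with no observation within `reach_sigma` standard
# deviations keep NaN.
smooth_periodic <- function(sums, counts, cell, sigma, reach_sigma = 3) {
  if (sigma <= 0) {
    v <- sums / counts
    v[counts == 0L] <- NaN
    return(list(values = v, support = counts > 0L))
  }
  nx <- nrow(sums); ny <- ncol(sums)
  hx <- min(nx %/% 2, ceiling(reach_sigma * sigma / cell[1]))
  hy <- min(ny %/% 2, ceiling(reach_sigma * sigma / cell[2]))
  num <- matrix(0, nx, ny); den <- matrix(0, nx, ny)
  reach <- matrix(0, nx, ny)
  shift_idx <- function(n, d) ((seq_len(n) - 1L + d) %% n) + 1L
  for (di in -hx:hx) {
    ix <- shift_idx(nx, di)
    for (dj in -hy:hy) {
      d2 <- (di * cell[1])^2 + (dj * cell[2])^2
      k <- exp(-d2 / (2 * sigma^2))
      iy <- shift_idx(ny, dj)
      num <- num + k * sums[ix, iy, drop = FALSE]
      den <- den + k * counts[ix, iy, drop = FALSE]
      if (d2 <= (reach_sigma * sigma)^2)
        reach <- reach + counts[ix, iy, drop = FALSE]
    }
  }
  v <- num / den
  v[den == 0 | reach == 0] <- NaN
  list(values = v, support = reach > 0)
}

#' Time-averaged headgroup-height surface of one leaflet
#'
#' Accumulates DPPC phosphorus z over all frames onto the grid, then applies
#' periodic Gaussian smoothing. Cells with no observation within
#' `3 * sigma` are flagged empty (NaN).
#'
#' @param traj,top Trajectory and topology.
#' @param assignment A [assign_leaflets()] result.
#' @param leaflet `"upper"` or `"lower"`.
#' @param grid_cell Cell edge, nm (default 0.5).
#' @param sigma Smoothing standard deviation, nm (default 1.0).
#' @param frames Frame indices to average over (default all).
#' @return A `grid_map` of headgroup height (nm).
#' @export
surface_map <- function(traj, top, assignment, leaflet = c("upper", "lower"),
                        grid_cell = 0.5, sigma = 1.0, frames = NULL) {
  leaflet <- match.arg(leaflet)
  if (grid_cell <= 0) stop("config error: grid_cell must be > 0")
  frames <- frames %||% seq_len(n_frames(traj))
  box <- traj$box[1, ]
  nd <- grid_dims(box, grid_cell)
  heads <- vapply(top$molecules,
                  function(m) if (m$species == "DPPC") m$head else NA_integer_,
                  1L)
  ids <- topology_ids(top)
  lab <- assignment$labels$label[match(ids, assignment$labels$molecule)]
  sel <- which(!is.na(heads) & lab == leaflet)
  if (!length(sel)) stop("degenerate geometry: no DPPC in ", leaflet,
                         " leaflet")
  sums <- matrix(0, nd[1], nd[2]); cnts <- matrix(0L, nd[1], nd[2])
  for (f in frames) {
    p <- traj$positions[[f]]
    xy <- p[heads[sel], 1:2, drop = FALSE]
    acc <- grid_accumulate(xy, p[heads[sel], 3], traj$box[f, ], nd[1], nd[2])
    sums <- sums + acc$sums; cnts <- cnts + acc$counts
  }
  # Per-cell time averages; unvisited cells take the value of their nearest
  # data before smoothing, then all cells are smoothed with equal weight.
  # This keeps interfaces at the geometric midpoint of data gaps: neither
  # lipid density nor mobility contrasts between regions (which control how
  # many distinct cells a region's heads visit) can drag them sideways.
  means <- sums / pmax(cnts, 1L)
  means[cnts == 0L] <- NaN
  if (sigma > 0) {
    filled <- fill_nearest(means)
    ones <- matrix(1L, nd[1], nd[2])
    sm <- smooth_periodic(filled, ones, box[1:2] / nd, sigma)
    # cells with no observation within 3 sigma stay flagged empty
    reach <- smooth_periodic(matrix(0, nd[1], nd[2]), (cnts > 0L) * 1L,
                             box[1:2] / nd, sigma)
    vals <- sm$values
    vals[!reach$support] <- NaN
  } else vals <- means
  new_grid_map(vals, cnts, box, unit = "nm")
}

#' Membrane thickness map (upper surface minus lower surface)
#'
#' @inheritParams surface_map
#' @return A `grid_map` of local bilayer thickness (nm).
#' @export
thickness_map <- function(traj, top, assignment, grid_cell = 0.5,
                          sigma = 1.0, frames = NULL) {
  up <- surface_map(traj, top, assignment, "upper", grid_cell, sigma, frames)
  lo <- surface_map(traj, top, assignment, "lower", grid_cell, sigma, frames)
  new_grid_map(up$values - lo$values, pmin(up$counts, lo$counts),
               up$box, unit = "nm")
}

#' Local chain-order map of one leaflet
#'
#' Each chain contributes its time-averaged chain-mean order (-S_CD) to the
#' grid cell containing its site (chain-carbon centroid projected to the
#' membrane plane) in every frame; the map is the per-cell mean.
#'
#' @param pco A [per_chain_order()] result.
#' @param traj,top,assignment,leaflet,grid_cell,frames As in [surface_map()].
#' @param sigma Optional periodic Gaussian smoothing, nm (default 0 = none).
#' @return A `grid_map` (dimensionless -S_CD).
#' @export
order_map <- function(pco, traj, top, assignment,
                      leaflet = c("upper", "lower"), grid_cell = 0.5,
                      sigma = 0, frames = NULL) {
  leaflet <- match.arg(leaflet)
  if (grid_cell <= 0) stop("config error: grid_cell must be > 0")
  frames <- frames %||% seq_len(n_frames(traj))
  box <- traj$box[1, ]
  nd <- grid_dims(box, grid_cell)
  cm <- attr(pco, "chain_means")
  lab <- assignment$labels$label[match(cm$molecule,
                                       assignment$labels$molecule)]
  cm <- cm[lab == leaflet & !is.na(lab), , drop = FALSE]
  if (!nrow(cm)) stop("no chains with computed order in ", leaflet,
                      " leaflet")
  # carbon atom lists per retained chain, for the site projection
  mol_idx <- match(cm$molecule, topology_ids(top))
  carbon_sets <- purrr::map2(mol_idx, cm$chain, function(i, lbl) {
    chs <- top$molecules[[i]]$chains
    chs[[which(vapply(chs, function(c) c$label, "") == lbl)[1]]]$carbons
  })
  sums <- matrix(0, nd[1], nd[2]); cnts <- matrix(0L, nd[1], nd[2])
  for (f in frames) {
    p <- traj$positions[[f]]; bx <- traj$box[f, ]
    xy <- t(vapply(carbon_sets, function(ix)
      periodic_centroid(p[ix, , drop = FALSE], bx)[1:2], numeric(2)))
    acc <- grid_accumulate(xy, cm$order, bx, nd[1], nd[2])
    sums <- sums + acc$sums; cnts <- cnts + acc$counts
  }
  sm <- smooth_periodic(sums, cnts, box[1:2] / nd, sigma)
  new_grid_map(sm$values, cnts, box, unit = "-S_CD")
}

#' Jump map: mean in-plane displacement per time window
#'
#' For every window of length `window` ns, each lipid of the leaflet
#' contributes the magnitude of its unwrapped lateral displacement over that
#' window to the cell of its start position; cells average over windows and
#' lipids. Low values mark immobile, gel-like regions.
#'
#' @inheritParams surface_map
#' @param window Window length, ns (default 1).
#' @return A `grid_map` of mean displacement (nm).
#' @export
jump_map <- function(traj, top, assignment, leaflet = c("upper", "lower"),
                     window = 1, grid_cell = 0.5) {
  leaflet <- match.arg(leaflet)
  if (grid_cell <= 0) stop("config error: grid_cell must be > 0")
  sp <- traj$spacing
  if (is.na(sp) || window < sp)
    stop("sampling error: window shorter than the frame spacing")
  k <- round(window / sp)
  nw <- (n_frames(traj) - 1L) %/% k
  if (nw < 1L) stop("sampling error: trajectory shorter than one window")
  box <- traj$box[1, ]
  nd <- grid_dims(box, grid_cell)
  ids <- topology_ids(top)
  lab <- assignment$labels$label[match(ids, assignment$labels$molecule)]
  sel <- which(lab == leaflet)
  if (!length(sel)) stop("degenerate geometry: empty leaflet")
  refs <- lapply(seq_len(nw * k + 1L),
                 function(f) reference_points_frame(traj, top, f)[sel, 1:2,
                                                                  drop = FALSE])
  sums <- matrix(0, nd[1], nd[2]); cnts <- matrix(0L, nd[1], nd[2])
  for (w in seq_len(nw)) {
    f0 <- (w - 1L) * k + 1L
    # unwrap across the window frame-by-frame
    disp <- matrix(0, length(sel), 2)
    for (f in f0:(f0 + k - 1L)) {
      st <- refs[[f + 1L]] - refs[[f]]
      st[, 1] <- min_image(st[, 1], box[1]); st[, 2] <- min_image(st[, 2], box[2])
      disp <- disp + st
    }
    mag <- sqrt(rowSums(disp^2))
    acc <- grid_accumulate(refs[[f0]], mag, box, nd[1], nd[2])
    sums <- sums + acc$sums; cnts <- cnts + acc$counts
  }
  v <- sums / cnts; v[cnts == 0L] <- NaN
  new_grid_map(v, cnts, box, unit = "nm")
}

#' Interleaflet order-correlation joint histogram
#'
#' Joint distribution of co-located local order in the two leaflets,
#' measured on a common grid. Mass concentrated on the diagonal indicates
#' membrane registry (ordered regions facing ordered regions).
#'
#' @param upper,lower `grid_map`s of local order on the same grid.
#' @param bins Histogram bin edges over -S_CD.
#' @param band Half-width w of the diagonal band |upper - lower| <= w.
#' @return A `joint_order_histogram`: tibble of bin masses with attributes
#'   `pearson_r`, `band_mass`, `band`, `breaks`, `n_cells`.
#' @export
interleaflet_histogram <- function(upper, lower,
                                   bins = seq(-0.1, 0.55, by = 0.025),
                                   band = 0.05) {
  if (!all(dim(upper$values) == dim(lower$values)))
    stop("alignment error: maps must share the same grid")
  u <- as.vector(upper$values); l <- as.vector(lower$values)
  ok <- is.finite(u) & is.finite(l)
  u <- u[ok]; l <- l[ok]
  if (!length(u)) stop("no co-occupied cells")
  clampv <- function(x) pmin(pmax(x, bins[1]), bins[length(bins)] - 1e-12)
  iu <- findInterval(clampv(u), bins, rightmost.closed = TRUE)
  il <- findInterval(clampv(l), bins, rightmost.closed = TRUE)
  nb <- length(bins) - 1L
  h <- matrix(0, nb, nb)
  for (k in seq_along(iu)) h[iu[k], il[k]] <- h[iu[k], il[k]] + 1
  h <- h / sum(h)
  mid <- (bins[-1] + bins[-length(bins)]) / 2
  out <- tibble::tibble(upper = rep(mid, times = nb),
                        lower = rep(mid, each = nb),
                        mass = as.vector(h))
  r <- if (stats::sd(u) > 0 && stats::sd(l) > 0) stats::cor(u, l) else NA_real_
  structure(out, pearson_r = r, band_mass = mean(abs(u - l) <= band),
            band = band, breaks = bins, n_cells = length(u),
            class = c("joint_order_histogram", class(out)))
}

#' @export
print.joint_order_histogram <- function(x, ...) {
  cat("<joint_order_histogram> ", attr(x, "n_cells"), " cells, Pearson r = ",
      sprintf("%.3f", attr(x, "pearson_r")), ", diagonal band (w = ",
      attr(x, "band"), ") mass = ", sprintf("%.3f", attr(x, "band_mass")),
      "\n", sep = "")
  invisible(x)
}

#' Area per lipid of one leaflet
#'
#' `Lx * Ly / N` with N the number of lipid molecules assigned to the
#' leaflet; cholesterol is counted by default (`count_sterols = FALSE`
#' excludes it from the denominator).
#'
#' @param traj,top,assignment As elsewhere; `frame` picks the box used.
#' @param leaflet `"upper"` or `"lower"`.
#' @param count_sterols Count sterols in the denominator?
#' @param frame Frame index (default 1).
#' @return Area per lipid, nm^2.
#' @export
area_per_lipid <- function(traj, top, assignment,
                           leaflet = c("upper", "lower"),
                           count_sterols = TRUE, frame = 1L) {
  leaflet <- match.arg(leaflet)
  lab <- assignment$labels
  keep <- lab$label == leaflet
  if (!count_sterols) keep <- keep & !is_sterol(lab$species)
  n <- sum(keep)
  if (n == 0L) stop("degenerate geometry: empty leaflet")
  prod(traj$box[frame, 1:2]) / n
}
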