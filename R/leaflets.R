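# Leaflet assignment. DPPC is assigned by headgroup-phosphorus height
# relative to the local bilayer midplane, sterols by ring-centroid height;
# the midplane is the per-cell mean of the two smoothed phosphorus surfaces,
# so rippled membranes are handled. DPPC labels are constant over the
# analysis window; sterols (flip-capable) are labelled per frame.

#' Assign lipids to leaflets
#'
#' Two-stage, local-midplane rule: a first midplane estimate is the smoothed
#' per-cell mean height of all headgroup reference points (both leaflets
#' together); molecules are split by the sign of their height relative to
#' it, the two phosphorus surfaces are rebuilt per leaflet, and the final
#' midplane is their per-cell mean, against which sterols are re-labelled
#' frame by frame.
#'
#' @param traj,top Trajectory and topology.
#' @param grid_cell Midplane grid cell, nm.
#' @param sigma Midplane smoothing, nm.
#' @return A `leaflet_assignment`: list with `labels` (tibble `molecule`,
#'   `species`, `label` -- the consensus label), `sterol_frames` (tibble
#'   `molecule`, `frame`, `label` for sterols), `midplane` (a `grid_map` of
#'   local mid-height, nm).
#' @export
assign_leaflets <- function(traj, top, grid_cell = 1.0, sigma = 1.0) {
  if (grid_cell <= 0) stop("config error: grid_cell must be > 0")
  nf <- n_frames(traj)
  box <- traj$box[1, ]
  nd <- grid_dims(box, grid_cell)
  ids <- topology_ids(top)
  species <- topology_species(top)
  nm <- length(ids)

  # reference heights and xy per molecule per frame
  refs <- array(NA_real_, c(nf, nm, 3))
  for (f in seq_len(nf)) refs[f, , ] <- reference_points_frame(traj, top, f)

  # stage 1: joint midplane from all reference points
  sums <- matrix(0, nd[1], nd[2]); cnts <- matrix(0L, nd[1], nd[2])
  for (f in seq_len(nf)) {
    acc <- grid_accumulate(refs[f, , 1:2, drop = FALSE][1, , ],
                           refs[f, , 3], traj$box[f, ], nd[1], nd[2])
    sums <- sums + acc$sums; cnts <- cnts + acc$counts
  }
  mid0 <- smooth_periodic(sums, cnts, box[1:2] / nd, max(sigma, grid_cell))
  height_vs <- function(f, midvals) {
    ij <- grid_cell_index(refs[f, , 1:2, drop = FALSE][1, , ],
                          traj$box[f, ], nd[1], nd[2])
    refs[f, , 3] - midvals[cbind(ij[, 1], ij[, 2])]
  }
  h0 <- t(vapply(seq_len(nf), function(f) height_vs(f, mid0$values),
                 numeric(nm)))
  lab0 <- ifelse(colMeans(h0) >= 0, "upper", "lower")

  dppc <- species == "DPPC"
  if (!any(lab0[dppc] == "upper") || !any(lab0[dppc] == "lower"))
    stop("degenerate geometry: a leaflet has zero lipids")

  # stage 2: per-leaflet phosphorus surfaces -> final midplane
  heads <- vapply(top$molecules, function(m) m$head, 1L)
  surf <- function(side) {
    sel <- which(dppc & lab0 == side)
    s <- matrix(0, nd[1], nd[2]); c <- matrix(0L, nd[1], nd[2])
    for (f in seq_len(nf)) {
      p <- traj$positions[[f]]
      acc <- grid_accumulate(p[heads[sel], 1:2, drop = FALSE],
                             p[heads[sel], 3], traj$box[f, ], nd[1], nd[2])
      s <- s + acc$sums; c <- c + acc$counts
    }
    smooth_periodic(s, c, box[1:2] / nd, sigma)$values
  }
  midv <- (surf("upper") + surf("lower")) / 2
  h <- t(vapply(seq_len(nf), function(f) height_vs(f, midv), numeric(nm)))

  label <- ifelse(colMeans(h) >= 0, "upper", "lower")
  # DPPC labels are window-constant by contract; sterols may flip
  sterol <- is_sterol(species)
  sterol_frames <- if (any(sterol)) {
    tibble::tibble(
      molecule = rep(ids[sterol], each = nf),
      frame = rep(seq_len(nf), times = sum(sterol)),
      label = ifelse(as.vector(h[, sterol, drop = FALSE]) >= 0,
                     "upper", "lower"))
  } else tibble::tibble(molecule = character(), frame = integer(),
                        label = character())

  if (!any(label[dppc] == "upper") || !any(label[dppc] == "lower"))
    stop("degenerate geometry: a leaflet has zero lipids")

  structure(list(
    labels = tibble::tibble(molecule = ids, species = species,
                            label = label),
    sterol_frames = sterol_frames,
    midplane = new_grid_map(midv, matrix(1L, nd[1], nd[2]), box,
                            unit = "nm"),
    heights = h),
    class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  tb <- table(x$labels$label)
  cat("<leaflet_assignment> ", paste(names(tb), tb, sep = ": ",
                                     collapse = ", "), "\n", sep = "")
  invisible(x)
}
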