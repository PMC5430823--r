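# Periodic-geometry helpers shared by all analysis stages.
# All coordinates are in nm; boxes are orthorhombic edge lengths (Lx, Ly, Lz).

#' Wrap coordinates into the primary periodic box
#'
#' @param x Numeric vector (or matrix column) of coordinates, nm.
#' @param L Box edge length, nm.
#' @return Coordinates wrapped into `[0, L)`.
#' @export
wrap_periodic <- function(x, L) {
  stopifnot(is.numeric(L), L > 0)
  x - floor(x / L) * L
}

#' Minimum-image convention for coordinate differences
#'
#' @param d Numeric differences, nm.
#' @param L Box edge length, nm.
#' @return Differences folded into `[-L/2, L/2)`.
#' @export
min_image <- function(d, L) {
  stopifnot(is.numeric(L), L > 0)
  d - round(d / L) * L
}

#' Periodic distance between 2D points
#'
#' @param a,b Length-2 numeric vectors or n x 2 matrices (x, y), nm.
#' @param box Length-2 (or longer; first two used) box edges, nm.
#' @return Euclidean distances under the minimum image, nm.
#' @export
periodic_distance <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  dx <- min_image(a[, 1] - b[, 1], box[1])
  dy <- min_image(a[, 2] - b[, 2], box[2])
  sqrt(dx^2 + dy^2)
}

# All pairwise periodic 2D distances; n x n symmetric matrix.
pairwise_periodic_dist <- function(xy, box) {
  dx <- min_image(outer(xy[, 1], xy[, 1], `-`), box[1])
  dy <- min_image(outer(xy[, 2], xy[, 2], `-`), box[2])
  sqrt(dx^2 + dy^2)
}

# Unwrap a time series of (possibly wrapped) positions by minimum-image
# continuation: each step is folded into [-L/2, L/2) and accumulated.
# xy: n_frames x k matrix, L: box edge per column (recycled).
unwrap_series <- function(xy, L) {
  xy <- rbind(xy)
  if (nrow(xy) < 2L) return(xy)
  L <- rep_len(L, ncol(xy))
  steps <- diff(xy)
  for (j in seq_len(ncol(xy))) steps[, j] <- min_image(steps[, j], L[j])
  out <- apply(rbind(xy[1, , drop = FALSE], steps), 2, cumsum)
  rbind(out)
}

# Periodic centroid of a point cloud: positions are made contiguous with the
# first point via minimum image before averaging, then wrapped back.
periodic_centroid <- function(pos, box) {
  pos <- rbind(pos)
  ref <- pos[1, ]
  for (j in 1:3) pos[, j] <- ref[j] + min_image(pos[, j] - ref[j], box[j])
  colMeans(pos)
}

# Second Legendre polynomial of a cosine.
p2 <- function(x) 0.5 * (3 * x^2 - 1)
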