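# Region classification: segment the membrane plane into hexagonal-core /
# ordered / disordered classes from the (smoothed, time-averaged) thickness
# map, and track per-class area over time for domain-shrinkage analyses.

REGION_CLASSES <- c("disordered", "ordered", "core")

#' Classify the membrane plane by local thickness
#'
#' Cells below `t1` are disordered, `[t1, t2)` ordered, `>= t2` core.
#' `thresholds = "auto"` fits a 3-component 1D Gaussian mixture to the
#' thickness histogram and places the thresholds at the density crossing
#' points between adjacent components. Components that do not separate
#' (no crossing between adjacent means) raise an error with guidance.
#' Contiguous patches smaller than `min_size` cells (4-connectivity,
#' periodic) are reassigned to the dominant neighbouring class to suppress
#' speckle.
#'
#' @param thickness A thickness `grid_map`.
#' @param thresholds Length-2 numeric `(t1, t2)` with `t1 < t2`, or
#'   `"auto"`.
#' @param min_size Minimum domain size in cells (default 4).
#' @param fill_empty Fill empty (NaN) cells by iterative 4-neighbour
#'   averaging before thresholding (default TRUE), so thin data gaps are
#'   assigned to the nearest phase instead of being dropped. Heavily
#'   smoothed maps have no empty cells and are unaffected.
#' @return A `region_map`: list with `labels` (character matrix), `map`
#'   (integer `grid_map`, 1 = disordered, 2 = ordered, 3 = core),
#'   `thresholds`, `areas` (tibble `class`, `area` in nm^2), `boundary`
#'   (logical matrix: cells with a differently-labelled 4-neighbour).
#' @export
classify <- function(thickness, thresholds = "auto", min_size = 4L,
                     fill_empty = TRUE) {
  v <- thickness$values
  if (fill_empty) v <- fill_nearest(v)
  if (identical(thresholds, "auto")) {
    thresholds <- auto_thresholds(v[is.finite(v)])
  } else {
    if (length(thresholds) != 2L || !(thresholds[1] < thresholds[2]))
      stop("config error: thresholds must satisfy t1 < t2")
  }
  lab <- matrix(NA_integer_, nrow(v), ncol(v))
  lab[is.finite(v)] <- 1L + (v[is.finite(v)] >= thresholds[1]) +
    (v[is.finite(v)] >= thresholds[2])
  lab <- despeckle(lab, min_size)
  region_map_from_labels(lab, thickness, thresholds)
}

region_map_from_labels <- function(lab, thickness, thresholds) {
  cell_area <- prod(thickness$cell)
  areas <- tibble::tibble(
    class = REGION_CLASSES,
    area = vapply(1:3, function(k) sum(lab == k, na.rm = TRUE) * cell_area,
                  numeric(1)))
  structure(list(labels = matrix(REGION_CLASSES[lab], nrow(lab), ncol(lab)),
                 map = new_grid_map(`[<-`(lab * 1.0, is.na(lab), NaN),
                                    matrix(1L, nrow(lab), ncol(lab)) -
                                      is.na(lab),
                                    thickness$box, unit = "class"),
                 thresholds = thresholds, areas = areas,
                 boundary = boundary_cells(lab),
                 cell = thickness$cell, box = thickness$box),
            class = "region_map")
}

# Crossing points of a 3-component Gaussian mixture fitted to x by EM
# (quantile-initialized, unequal variances).
auto_thresholds <- function(x) {
  fit <- tryCatch(gmm3_em(x), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(c(fit$mu, fit$sd, fit$pro))) ||
      min(fit$pro) < 1e-4)
    stop("auto thresholding failed to fit 3 modes; supply thresholds ",
         "(t1, t2) explicitly")
  mu <- fit$mu; sd <- fit$sd; pro <- fit$pro
  crossing <- function(i) {
    f <- function(t) pro[i] * stats::dnorm(t, mu[i], sd[i]) -
      pro[i + 1] * stats::dnorm(t, mu[i + 1], sd[i + 1])
    if (mu[i + 1] - mu[i] < 1e-9 || f(mu[i]) * f(mu[i + 1]) > 0)
      return(NA_real_)
    stats::uniroot(f, c(mu[i], mu[i + 1]))$root
  }
  t1 <- crossing(1); t2 <- crossing(2)
  if (!is.finite(t1) || !is.finite(t2))
    stop("auto thresholding failed to find 3 separated modes; supply ",
         "thresholds (t1, t2) explicitly")
  c(t1, t2)
}

# Plain EM for a 1D 3-component Gaussian mixture. Initialized from a
# k-means partition seeded at evenly spaced values over the data range
# (deterministic; quantile seeding can put two components on one dominant
# mode when class sizes are very unequal).
gmm3_em <- function(x, max_iter = 500L, tol = 1e-10) {
  K <- 3L
  km <- stats::kmeans(x, centers = matrix(seq(min(x), max(x),
                                              length.out = K)))
  ord0 <- order(km$centers)
  mu <- as.numeric(km$centers[ord0])
  sd <- vapply(ord0, function(k) {
    v <- stats::sd(x[km$cluster == k])
    if (!is.finite(v) || v < 1e-6) diff(range(x)) / 50 else v
  }, numeric(1))
  pro <- as.numeric(table(factor(km$cluster, levels = ord0))) / length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:K, function(k)
      pro[k] * stats::dnorm(x, mu[k], sd[k]), numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    pro <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sd <- sqrt(pmax(colSums(resp * outer(x, mu, "-")^2) / nk, 1e-12))
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], sd = sd[ord], pro = pro[ord])
}

# Fill NaN cells by repeated averaging over finite 4-neighbours (periodic);
# converges outward from the data, so a gap cell takes the value of its
# nearest occupied cells.
fill_nearest <- function(v, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    empty <- !is.finite(v)
    if (!any(empty)) break
    sh <- shift4(v)
    s <- matrix(0, nrow(v), ncol(v)); n <- matrix(0, nrow(v), ncol(v))
    for (m in sh) {
      fin <- is.finite(m)
      s[fin] <- s[fin] + m[fin]
      n <- n + fin
    }
    fillable <- empty & n > 0
    if (!any(fillable)) break
    v[fillable] <- s[fillable] / n[fillable]
  }
  v
}

# Periodic 4-neighbour shifts of a matrix.
shift4 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  list(m[c(nx, 1:(nx - 1)), , drop = FALSE],
       m[c(2:nx, 1), , drop = FALSE],
       m[, c(ny, 1:(ny - 1)), drop = FALSE],
       m[, c(2:ny, 1), drop = FALSE])
}

boundary_cells <- function(lab) {
  b <- matrix(FALSE, nrow(lab), ncol(lab))
  for (s in shift4(lab)) {
    diffc <- !is.na(lab) & !is.na(s) & lab != s
    b <- b | diffc
  }
  b
}

# Reassign connected components (4-connectivity, periodic) smaller than
# min_size to the most common neighbouring label.
despeckle <- function(lab, min_size) {
  if (min_size <= 1L) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  comp <- matrix(0L, nx, ny)
  nid <- 0L
  for (start in which(!is.na(lab))) {
    if (comp[start] != 0L) next
    nid <- nid + 1L
    queue <- start
    comp[start] <- nid
    val <- lab[start]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- ((cur - 1L) %% nx) + 1L; j <- ((cur - 1L) %/% nx) + 1L
      nbrs <- c(((i %% nx) + 1L) + nx * (j - 1L),
                (((i - 2L) %% nx) + 1L) + nx * (j - 1L),
                i + nx * ((j %% ny)),
                i + nx * (((j - 2L) %% ny)))
      for (nb in nbrs) {
        if (comp[nb] == 0L && !is.na(lab[nb]) && lab[nb] == val) {
          comp[nb] <- nid
          queue <- c(queue, nb)
        }
      }
    }
  }
  sizes <- tabulate(comp[comp > 0L])
  small <- which(sizes < min_size)
  if (!length(small)) return(lab)
  sh <- shift4(lab)
  for (cid in small) {
    cells <- which(comp == cid)
    nb_lab <- unlist(lapply(sh, function(s) s[cells]))
    nb_lab <- nb_lab[!is.na(nb_lab) & !(nb_lab %in% lab[cells][1])]
    if (length(nb_lab))
      lab[cells] <- as.integer(names(which.max(table(nb_lab))))
  }
  lab
}

#' @export
print.region_map <- function(x, ...) {
  a <- x$areas
  cat("<region_map> thresholds (", sprintf("%.3f, %.3f", x$thresholds[1],
                                           x$thresholds[2]), ") nm; areas: ",
      paste(sprintf("%s %.1f nm^2", a$class, a$area), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy view of a region map
#' @param x A `region_map`.
#' @param ... Unused.
#' @return Tibble `x`, `y`, `class`, `boundary`.
#' @export
as_tibble.region_map <- function(x, ...) {
  tb <- as_tibble.grid_map(x$map)
  tb$class <- REGION_CLASSES[tb$value]
  tb$boundary <- as.vector(x$boundary)
  dplyr::select(tb, "x", "y", "class", "boundary")
}

#' Track per-class area over trajectory windows
#'
#' Splits the trajectory into `n_windows` equal windows, classifies the
#' windowed thickness map of each, and reports per-class areas and the
#' ratio of the final to initial ordered-plus-core area (the
#' domain-shrinkage statistic).
#'
#' @param traj,top,assignment As elsewhere.
#' @param n_windows Number of windows (>= 2).
#' @param grid_cell,sigma Thickness-map parameters. The default smoothing
#'   (0.5 nm) is narrower than the display-map default: the mid-level
#'   contour of a Gaussian-blurred disc shifts inward by about
#'   `sigma^2 / (2 R)`, so classification maps keep sigma small to bound
#'   the curvature bias on domain areas.
#' @param thresholds,min_size Passed to [classify()].
#' @return Tibble `window`, `t_mid` (ns), `disordered`, `ordered`, `core`
#'   (areas, nm^2), with attribute `area_ratio` = final / initial
#'   (ordered + core).
#' @export
track_domain_area <- function(traj, top, assignment, n_windows = 10L,
                              grid_cell = 0.5, sigma = 0.5,
                              thresholds = "auto", min_size = 4L) {
  if (n_windows < 2L) stop("need at least 2 windows")
  nf <- n_frames(traj)
  bounds <- floor(seq(0, nf, length.out = n_windows + 1L))
  rows <- purrr::map_dfr(seq_len(n_windows), function(w) {
    frames <- (bounds[w] + 1L):bounds[w + 1L]
    tm <- thickness_map(traj, top, assignment, grid_cell, sigma, frames)
    rm <- classify(tm, thresholds, min_size)
    a <- stats::setNames(rm$areas$area, rm$areas$class)
    tibble::tibble(window = w, t_mid = mean(traj$times[frames]),
                   disordered = a[["disordered"]],
                   ordered = a[["ordered"]], core = a[["core"]])
  })
  first <- rows$ordered[1] + rows$core[1]
  last <- rows$ordered[n_windows] + rows$core[n_windows]
  structure(rows, area_ratio = if (first > 0) last / first else NA_real_,
            class = c("domain_area_series", class(rows)))
}

#' Minimum periodic distance from a point to the region boundary
#'
#' @param point Length-2 (x, y), nm.
#' @param region A `region_map` with a non-empty boundary.
#' @return Distance to the nearest boundary-cell centre, nm.
#' @export
boundary_distance <- function(point, region) {
  bc <- which(region$boundary, arr.ind = TRUE)
  if (!nrow(bc)) stop("empty boundary")
  cx <- (bc[, 1] - 0.5) * region$cell[1]
  cy <- (bc[, 2] - 0.5) * region$cell[2]
  min(periodic_distance(cbind(cx, cy), point, region$box))
}

# Boundary distance for every cell centre (refine > 1: probe points on a
# finer sub-lattice, for unbiased shell-area fractions against continuous
# event positions).
boundary_distance_map <- function(region, refine = 1L) {
  bc <- which(region$boundary, arr.ind = TRUE)
  if (!nrow(bc)) stop("empty boundary")
  nx <- refine * nrow(region$boundary); ny <- refine * ncol(region$boundary)
  cx <- (seq_len(nx) - 0.5) * region$cell[1] / refine
  cy <- (seq_len(ny) - 0.5) * region$cell[2] / refine
  bx <- (bc[, 1] - 0.5) * region$cell[1]
  by <- (bc[, 2] - 0.5) * region$cell[2]
  dx <- min_image(outer(cx, bx, `-`), region$box[1])
  out <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) {
    dy <- min_image(cy[j] - by, region$box[2])
    out[, j] <- sqrt(apply(dx^2 + rep(dy^2, each = nx), 1, min))
  }
  out
}
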