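# Deuterium order parameters. S_CD = <(3 cos^2 theta - 1)/2> with theta the
# angle between the C-H bond and the membrane normal (z). Values are
# reported as -S_CD (positive for ordered chains), matching NMR convention.

#' Order parameter of a single C-H bond instance
#'
#' @param c_pos,h_pos Length-3 carbon and hydrogen positions, nm.
#' @param normal Membrane normal (any non-zero length).
#' @return `(3 cos^2 theta - 1) / 2` for this bond instance (the raw S_CD
#'   contribution, not negated).
#' @export
scd_bond <- function(c_pos, h_pos, normal = c(0, 0, 1)) {
  v <- h_pos - c_pos
  nv <- sqrt(sum(v^2)); nn <- sqrt(sum(normal^2))
  if (nv == 0) stop("geometry error: zero-length C-H bond vector")
  if (nn == 0) stop("geometry error: zero-length normal vector")
  p2(sum(v * normal) / (nv * nn))
}

#' Per-chain time-averaged order parameters
#'
#' For every chain carbon of every DPPC molecule, -S_CD is averaged over
#' both attached hydrogens and all frames of the analysis window. The
#' membrane normal is z. Per-molecule/per-chain scalar order (the mean over
#' the configured carbon range) is attached as the `chain_means` attribute.
#'
#' @param traj,top Trajectory and topology.
#' @param chain `"sn-2"` (default), `"sn-1"`, or `"both"`.
#' @param window Length of the averaging window in ns counted from the first
#'   frame (default: the whole trajectory).
#' @param carbon_range Carbons entering the chain-mean scalar (sn-2
#'   numbering; default 2:15 -- the terminal methyl is noisy).
#' @param reconstruct_hydrogens For hydrogen-free chains, reconstruct C-H
#'   directions as the two unit vectors perpendicular to the local
#'   C(i-1)->C(i+1) chain axis (all-trans geometry); off by default.
#' @return A `per_chain_order` tibble (`molecule`, `chain`, `carbon`,
#'   `scd` = mean -S_CD, `n_frames`), with attributes `chain_means`
#'   (tibble `molecule`, `chain`, `order`) and `molecule_means`.
#' @export
per_chain_order <- function(traj, top, chain = c("sn-2", "sn-1", "both"),
                            window = NULL, carbon_range = 2:15,
                            reconstruct_hydrogens = FALSE) {
  chain <- match.arg(chain)
  frames <- seq_len(n_frames(traj))
  if (!is.null(window)) {
    if (window > diff(range(traj$times)) + traj$spacing + 1e-9)
      stop("window longer than the trajectory")
    frames <- which(traj$times <= traj$times[1] + window + 1e-9)
  }
  bt <- bond_table(top, chain)
  if (!nrow(bt)) {
    if (!reconstruct_hydrogens)
      stop("topology error: no attached hydrogens for the selected chains ",
           "(set reconstruct_hydrogens = TRUE for united-atom input)")
    return(reconstructed_order(traj, top, chain, frames, carbon_range))
  }
  acc <- numeric(nrow(bt))
  for (f in frames) {
    p <- traj$positions[[f]]
    v <- p[bt$h_idx, , drop = FALSE] - p[bt$c_idx, , drop = FALSE]
    # atoms are wrapped independently; bonds never span half the box
    v[, 1] <- min_image(v[, 1], traj$box[f, 1])
    v[, 2] <- min_image(v[, 2], traj$box[f, 2])
    acc <- acc + p2(v[, 3] / sqrt(rowSums(v^2)))
  }
  bt$scd <- -acc / length(frames)
  out <- bt |>
    dplyr::group_by(.data$molecule, .data$chain, .data$carbon) |>
    dplyr::summarise(scd = mean(.data$scd), .groups = "drop") |>
    dplyr::mutate(n_frames = length(frames))
  finalize_pco(out, carbon_range, length(frames))
}

# Hydrogen reconstruction path: C-H directions from the local chain frame.
reconstructed_order <- function(traj, top, chain, frames, carbon_range) {
  rows <- list()
  for (m in top$molecules) {
    if (m$species != "DPPC") next
    for (ch in m$chains) {
      if (!identical(chain, "both") && !identical(ch$label, chain)) next
      nc <- length(ch$carbons)
      if (nc < 3L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        molecule = m$id, chain = ch$label, carbon = seq_len(nc - 2L) + 2L,
        prev = ch$carbons[seq_len(nc - 2L)],
        nxt = ch$carbons[seq_len(nc - 2L) + 2L])
    }
  }
  if (!length(rows)) stop("topology error: no chains selected")
  bt <- dplyr::bind_rows(rows)
  acc <- numeric(nrow(bt))
  for (f in frames) {
    p <- traj$positions[[f]]
    a <- p[bt$nxt, , drop = FALSE] - p[bt$prev, , drop = FALSE]
    a[, 1] <- min_image(a[, 1], traj$box[f, 1])
    a[, 2] <- min_image(a[, 2], traj$box[f, 2])
    a <- a / sqrt(rowSums(a^2))
    # two unit vectors perpendicular to the local axis a:
    # u1 = normalize(a x z) (x-hat where degenerate), u2 = a x u1
    u1 <- cbind(a[, 2], -a[, 1], 0)
    n1 <- sqrt(rowSums(u1^2))
    deg <- n1 < 1e-8
    u1[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3, byrow = TRUE)
    n1[deg] <- 1
    u1 <- u1 / n1
    u2 <- cbind(a[, 2] * u1[, 3] - a[, 3] * u1[, 2],
                a[, 3] * u1[, 1] - a[, 1] * u1[, 3],
                a[, 1] * u1[, 2] - a[, 2] * u1[, 1])
    acc <- acc + (p2(u1[, 3]) + p2(u2[, 3])) / 2
  }
  bt$scd <- -acc / length(frames)
  out <- dplyr::select(bt, "molecule", "chain", "carbon", "scd") |>
    dplyr::mutate(n_frames = length(frames))
  finalize_pco(out, carbon_range, length(frames))
}

finalize_pco <- function(out, carbon_range, nf) {
  cm <- out |>
    dplyr::filter(.data$carbon %in% carbon_range) |>
    dplyr::group_by(.data$molecule, .data$chain) |>
    dplyr::summarise(order = mean(.data$scd), .groups = "drop")
  mm <- cm |>
    dplyr::group_by(.data$molecule) |>
    dplyr::summarise(order = mean(.data$order), .groups = "drop")
  structure(out, chain_means = cm, molecule_means = mm,
            carbon_range = carbon_range, n_frames_used = nf,
            class = c("per_chain_order", class(out)))
}

default_order_breaks <- function() seq(-0.1, 0.55, by = 0.01)

#' Per-carbon distributions of per-chain time-averaged order
#'
#' Histograms the per-chain time averages carbon by carbon over shared bin
#' edges, normalized to unit mass per carbon. Values outside the bin range
#' are clamped into the edge bins so normalization is preserved.
#'
#' @param pco A [per_chain_order()] result.
#' @param breaks Shared bin edges over -S_CD (default 0.01-wide bins over
#'   `[-0.1, 0.55]`, resolving the gel/Lo/Ld modes).
#' @param provenance Optional label recorded with the distribution.
#' @return An `order_distribution`: list with `carbons`, `breaks`, `mass`
#'   (n_carbons x n_bins matrix, rows sum to 1), `provenance`.
#' @export
order_distribution <- function(pco, breaks = default_order_breaks(),
                               provenance = "") {
  if (!nrow(pco)) stop("empty selection: no chains to histogram")
  carbons <- sort(unique(pco$carbon))
  nb <- length(breaks) - 1L
  mass <- matrix(0, length(carbons), nb,
                 dimnames = list(carbons, NULL))
  for (i in seq_along(carbons)) {
    v <- pco$scd[pco$carbon == carbons[i]]
    v <- pmin(pmax(v, breaks[1]), breaks[length(breaks)] - 1e-12)
    h <- findInterval(v, breaks, rightmost.closed = TRUE)
    tb <- tabulate(h, nbins = nb)
    mass[i, ] <- tb / sum(tb)
  }
  new_order_distribution(carbons, breaks, mass, provenance)
}

new_order_distribution <- function(carbons, breaks, mass, provenance = "") {
  stopifnot(nrow(mass) == length(carbons), ncol(mass) == length(breaks) - 1L)
  s <- rowSums(mass)
  if (any(abs(s - 1) > 1e-9))
    stop("each per-carbon histogram must sum to 1 (off by ",
         max(abs(s - 1)), ")")
  structure(list(carbons = as.integer(carbons), breaks = breaks,
                 mass = mass, provenance = provenance),
            class = "order_distribution")
}

#' @export
print.order_distribution <- function(x, ...) {
  cat("<order_distribution> carbons ", min(x$carbons), "..", max(x$carbons),
      ", ", ncol(x$mass), " bins over [", x$breaks[1], ", ",
      x$breaks[length(x$breaks)], "]",
      if (nzchar(x$provenance)) paste0(" (", x$provenance, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Tidy view of an order distribution
#' @param x An `order_distribution`.
#' @param ... Unused.
#' @return Tibble with `carbon`, `scd` (bin centre), `mass`.
#' @export
as_tibble.order_distribution <- function(x, ...) {
  mid <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  tibble::tibble(carbon = rep(x$carbons, each = length(mid)),
                 scd = rep(mid, times = length(x$carbons)),
                 mass = as.vector(t(x$mass)))
}

#' Mean order profile of a distribution
#'
#' Per-carbon expectation of -S_CD under the histogram (bin-centre rule).
#'
#' @param dist An `order_distribution`.
#' @return An `order_profile` tibble with `carbon`, `scd`.
#' @export
mean_profile <- function(dist) {
  stopifnot(inherits(dist, "order_distribution"))
  mid <- (dist$breaks[-1] + dist$breaks[-length(dist$breaks)]) / 2
  out <- tibble::tibble(carbon = dist$carbons,
                        scd = as.vector(dist$mass %*% mid))
  structure(out, class = c("order_profile", class(out)))
}

#' Export an order distribution as CSV (+ JSON provenance header)
#' @param dist An `order_distribution`.
#' @param path CSV output path; a `.json` side-car records bins/provenance.
#' @return `path`, invisibly.
#' @export
write_order_distribution <- function(dist, path) {
  utils::write.csv(as_tibble.order_distribution(dist), path,
                   row.names = FALSE)
  jsonlite::write_json(list(provenance = dist$provenance,
                            breaks = dist$breaks, carbons = dist$carbons),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
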