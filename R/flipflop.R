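# Cholesterol flip-flop analysis: leaflet traces, hysteresis event
# detection, and localization of events relative to the domain boundary.
#
# Detector contract: a molecule commits a flip only when its height trace,
# having last been beyond +delta, passes beyond -delta and stays on the new
# side of the midplane for at least tau_min (and symmetrically). The commit
# time is the first crossing of the far threshold; excursions confined to
# (-delta, +delta) never count. Using the local (grid) midplane means
# membrane ripples do not fake events.

#' Leaflet-height trace of one sterol
#'
#' Ring-centroid z minus the local midplane height at the sterol's (x, y),
#' per frame.
#'
#' @param traj,top As elsewhere.
#' @param molecule Sterol molecule id.
#' @param assignment A [assign_leaflets()] result (provides the midplane),
#'   or a midplane `grid_map`.
#' @return Tibble `frame`, `time`, `x`, `y`, `height` (nm).
#' @export
leaflet_trace <- function(traj, top, molecule, assignment) {
  m <- topology_molecule(top, molecule)
  if (!is_sterol(m$species) && !length(m$ring_atoms))
    stop("molecule '", molecule, "' has no ring atoms")
  mid <- if (inherits(assignment, "grid_map")) assignment
         else assignment$midplane
  nx <- nrow(mid$values); ny <- ncol(mid$values)
  purrr::map_dfr(seq_len(n_frames(traj)), function(f) {
    pos <- traj$positions[[f]]; box <- traj$box[f, ]
    ct <- periodic_centroid(pos[m$ring_atoms, , drop = FALSE], box)
    ij <- grid_cell_index(rbind(ct[1:2]), mid$box, nx, ny)
    tibble::tibble(frame = f, time = traj$times[f],
                   x = wrap_periodic(ct[1], box[1]),
                   y = wrap_periodic(ct[2], box[2]),
                   height = ct[3] - mid$values[ij[1], ij[2]])
  })
}

#' Detect committed flip-flop events in a height trace
#'
#' @param trace Tibble with `time`, `height` (and optionally `x`, `y`,
#'   `molecule`), e.g. from [leaflet_trace()] or [scripted_flip_trace()].
#' @param delta Hysteresis half-width, nm (default 0.4).
#' @param tau_min Minimum dwell on the new side, ns (default 1).
#' @return A `flipflop_events` tibble: `molecule`, `time` (commit time,
#'   ns), `direction`, `x`, `y` (lateral position at the commit frame).
#' @export
detect_flipflops <- function(trace, delta = 0.4, tau_min = 1) {
  if (delta <= 0) stop("delta must be > 0")
  if (tau_min < 0) stop("tau_min must be >= 0")
  t <- trace$time; h <- trace$height
  n <- length(h)
  if (n < 2L || (t[n] - t[1]) < tau_min)
    stop("sampling error: trace shorter than tau_min")
  mol <- if ("molecule" %in% names(trace)) trace$molecule[1] else "trace"
  xs <- if ("x" %in% names(trace)) trace$x else rep(NA_real_, n)
  ys <- if ("y" %in% names(trace)) trace$y else rep(NA_real_, n)
  state <- 0  # last side established beyond +/- delta
  events <- list()
  i <- 1L
  while (i <= n) {
    if (state == 0 && abs(h[i]) >= delta) state <- sign(h[i])
    if (state != 0 && sign(h[i]) == -state && abs(h[i]) >= delta) {
      # candidate commit: must stay on the new side for >= tau_min
      jmax <- which(t >= t[i] + tau_min)
      ok_span <- if (length(jmax)) i:jmax[1] else i:n
      dwell_ok <- all(sign(h[ok_span]) == -state) &&
        (length(jmax) > 0 || (t[n] - t[i]) >= tau_min)
      if (dwell_ok) {
        events[[length(events) + 1L]] <- tibble::tibble(
          molecule = mol, time = t[i],
          direction = if (state > 0) "upper_to_lower" else "lower_to_upper",
          x = xs[i], y = ys[i])
        state <- -state
        i <- ok_span[length(ok_span)]
      }
    }
    i <- i + 1L
  }
  out <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(molecule = character(), time = numeric(),
                   direction = character(), x = numeric(), y = numeric())
  structure(out, delta = delta, tau_min = tau_min,
            class = c("flipflop_events", class(out)))
}

#' Detect flip-flops for every sterol in a trajectory
#'
#' @param traj,top,assignment As elsewhere.
#' @param delta,tau_min Passed to [detect_flipflops()].
#' @return A `flipflop_events` tibble over all sterols.
#' @export
detect_all_flipflops <- function(traj, top, assignment, delta = 0.4,
                                 tau_min = 1) {
  ids <- topology_ids(top)[is_sterol(topology_species(top))]
  evs <- purrr::map(ids, function(id) {
    tr <- leaflet_trace(traj, top, id, assignment)
    tr$molecule <- id
    detect_flipflops(tr, delta, tau_min)
  })
  out <- dplyr::bind_rows(evs)
  structure(out, delta = delta, tau_min = tau_min,
            class = c("flipflop_events", class(out)))
}

#' Boundary enrichment of flip-flop events
#'
#' Compares the fraction of events within `shell` nm of the domain boundary
#' against the area fraction of that shell, with a one-sided binomial test
#' against the area-fraction null.
#'
#' @param events A `flipflop_events` tibble (>= 1 event) with `x`, `y`.
#' @param region A `region_map` with non-empty boundary.
#' @param shell Shell width w, nm.
#' @return An `enrichment_report` with [tidy()] (per-event boundary
#'   distances) and [glance()] (`n`, `in_shell`, `area_fraction`,
#'   `event_fraction`, `ratio`, `p_value`).
#' @export
flipflop_boundary_enrichment <- function(events, region, shell) {
  if (!nrow(events)) stop("no events to analyse")
  # shell area fraction probed on a 2x refined sub-lattice, so continuous
  # event positions and the area measure see the same geometry
  dmap <- boundary_distance_map(region, refine = 2L)
  valid <- is.finite(region$map$values)[
    cbind(rep(ceiling(seq_len(nrow(dmap)) / 2), ncol(dmap)),
          rep(ceiling(seq_len(ncol(dmap)) / 2), each = nrow(dmap)))]
  area_fraction <- mean(dmap[valid] <= shell)
  d <- vapply(seq_len(nrow(events)), function(k)
    boundary_distance(c(events$x[k], events$y[k]), region), numeric(1))
  in_shell <- d <= shell
  test <- stats::binom.test(sum(in_shell), length(d), area_fraction,
                            alternative = "greater")
  structure(list(
    events = dplyr::mutate(events, boundary_distance = d,
                           in_shell = in_shell),
    shell = shell, area_fraction = area_fraction,
    event_fraction = mean(in_shell),
    ratio = mean(in_shell) / area_fraction,
    p_value = test$p.value),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_report> %d/%d events within %.2f nm of ",
                     "the boundary (shell area fraction %.3f): ratio %.2f, ",
                     "p = %.3g\n"),
              sum(x$events$in_shell), nrow(x$events), x$shell,
              x$area_fraction, x$ratio, x$p_value))
  invisible(x)
}

#' @export
tidy.enrichment_report <- function(x, ...) x$events

#' @export
glance.enrichment_report <- function(x, ...) {
  tibble::tibble(n = nrow(x$events), in_shell = sum(x$events$in_shell),
                 area_fraction = x$area_fraction,
                 event_fraction = x$event_fraction, ratio = x$ratio,
                 p_value = x$p_value)
}

#' Export flip-flop events as CSV
#' @param events A `flipflop_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
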