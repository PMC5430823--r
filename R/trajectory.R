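# Trajectory container and GRO/XYZ readers/writers.
#
# Conventions: coordinates in nm throughout (GRO native); XYZ files are
# assumed to be in Angstrom and are converted on read/write. Only
# orthorhombic boxes are supported -- the analyses are membrane-plane based.

NM_PER_ANGSTROM <- 0.1

#' Construct a trajectory object
#'
#' A trajectory is an ordered sequence of coordinate frames with a periodic
#' orthorhombic box, uniformly spaced in time.
#'
#' @param positions List of `n_atoms x 3` numeric matrices (nm), one per frame.
#' @param times Numeric vector of frame times, ns; strictly increasing and
#'   uniformly spaced (within `tol`).
#' @param box Numeric length-3 vector, or `n_frames x 3` matrix, of box edge
#'   lengths (Lx, Ly, Lz), nm.
#' @param tol Tolerance on spacing uniformity, ns.
#' @return An object of class `bilayer_trajectory` with fields `positions`,
#'   `times`, `box` (matrix), `n_atoms`, `spacing` (ns).
#' @export
new_trajectory <- function(positions, times, box, tol = 1e-6) {
  if (!is.list(positions) || length(positions) == 0L)
    stop("positions must be a non-empty list of coordinate matrices")
  n_atoms <- nrow(positions[[1]])
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    if (!is.matrix(p) || ncol(p) != 3L)
      stop("frame ", i, ": positions must be an n x 3 matrix")
    if (nrow(p) != n_atoms)
      stop("structure error: frame ", i, " has ", nrow(p),
           " atoms, expected ", n_atoms)
    if (!all(is.finite(p)))
      stop("frame ", i, ": non-finite coordinates")
  }
  if (length(times) != length(positions))
    stop("times must have one entry per frame")
  if (is.null(dim(box))) box <- matrix(box, nrow = length(positions),
                                       ncol = 3, byrow = TRUE)
  if (nrow(box) != length(positions) || ncol(box) != 3L)
    stop("box must be a length-3 vector or n_frames x 3 matrix")
  dimnames(box) <- NULL
  if (any(box <= 0)) stop("all box edges must be > 0")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    spacing <- stats::median(dt)
    if (any(abs(dt - spacing) > tol))
      stop("frame times are not uniformly spaced (tolerance ", tol, " ns)")
  } else spacing <- NA_real_
  structure(list(positions = positions, times = as.numeric(times),
                 box = box, n_atoms = n_atoms, spacing = spacing),
            class = "bilayer_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `bilayer_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$positions)

#' @export
print.bilayer_trajectory <- function(x, ...) {
  cat("<bilayer_trajectory> ", n_frames(x), " frames, ", x$n_atoms,
      " atoms, box ", paste(sprintf("%.3f", x$box[1, ]), collapse = " x "),
      " nm, spacing ", signif(x$spacing, 4), " ns\n", sep = "")
  invisible(x)
}

#' Tidy view of a trajectory frame
#' @param x A `bilayer_trajectory`.
#' @param frame Frame index (default all frames; can be large).
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time`, `atom`, `x`, `y`, `z`.
#' @export
as_tibble.bilayer_trajectory <- function(x, frame = NULL, ...) {
  idx <- if (is.null(frame)) seq_len(n_frames(x)) else frame
  purrr::map_dfr(idx, function(i) {
    p <- x$positions[[i]]
    tibble::tibble(frame = i, time = x$times[i], atom = seq_len(nrow(p)),
                   x = p[, 1], y = p[, 2], z = p[, 3])
  })
}

parse_box_line <- function(tokens, line_no) {
  v <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(v)) || !length(v) %in% c(3L, 9L))
    stop("parse error at line ", line_no, ": malformed box specification")
  if (length(v) == 9L && any(abs(v[4:9]) > 1e-9))
    stop("unsupported format: triclinic boxes are not supported ",
         "(line ", line_no, "); only orthorhombic boxes are handled")
  if (any(v[1:3] <= 0))
    stop("parse error at line ", line_no, ": box edges must be > 0")
  v[1:3]
}

parse_gro_time <- function(title) {
  m <- regmatches(title, regexec("t=\\s*([0-9eE.+-]+)", title))[[1]]
  if (length(m) == 2L) suppressWarnings(as.numeric(m[2])) else NA_real_
}

read_gro <- function(path, dt = 1) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(); boxes <- NULL
  i <- 1L; n_atoms_ref <- NA_integer_; fno <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    fno <- fno + 1L
    title <- lines[i]
    if (i + 1L > length(lines))
      stop("parse error at line ", i, ": truncated frame header")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat <= 0L)
      stop("parse error at line ", i + 1L, ": invalid atom count")
    if (is.na(n_atoms_ref)) n_atoms_ref <- nat
    else if (nat != n_atoms_ref)
      stop("structure error: frame ", fno, " has ", nat,
           " atoms, expected ", n_atoms_ref)
    last <- i + 1L + nat
    if (last + 1L > length(lines))
      stop("parse error at line ", length(lines), ": truncated frame")
    atom_lines <- lines[(i + 2L):last]
    xs <- suppressWarnings(as.numeric(substr(atom_lines, 21L, 28L)))
    ys <- suppressWarnings(as.numeric(substr(atom_lines, 29L, 36L)))
    zs <- suppressWarnings(as.numeric(substr(atom_lines, 37L, 44L)))
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad))
      stop("parse error at line ", i + 1L + bad[1],
           ": malformed coordinate record")
    box <- parse_box_line(strsplit(trimws(lines[last + 1L]), "\\s+")[[1]],
                          last + 1L)
    frames[[fno]] <- cbind(xs, ys, zs, deparse.level = 0)
    times[fno] <- parse_gro_time(title)
    boxes <- rbind(boxes, box)
    i <- last + 2L
  }
  if (fno == 0L) stop("parse error: no frames found in ", path)
  if (any(is.na(times))) times <- (seq_len(fno) - 1) * dt
  new_trajectory(frames, times, boxes)
}

write_gro <- function(traj, path, top = NULL) {
  names <- gro_atom_labels(traj$n_atoms, top)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    p <- traj$positions[[f]]
    writeLines(sprintf("synthetic bilayer frame %d t= %.6f", f,
                       traj$times[f]), con)
    writeLines(sprintf("%5d", traj$n_atoms), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       names$resid %% 100000L, names$resname, names$atom,
                       seq_len(traj$n_atoms) %% 100000L,
                       p[, 1], p[, 2], p[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1],
                       traj$box[f, 2], traj$box[f, 3]), con)
  }
  invisible(path)
}

# Per-atom residue ids / names for GRO output; generic when no topology.
gro_atom_labels <- function(n_atoms, top = NULL) {
  if (is.null(top))
    return(list(resid = rep(1L, n_atoms), resname = rep("MOL", n_atoms),
                atom = sprintf("X%d", seq_len(n_atoms) %% 1000L)))
  resid <- integer(n_atoms); resname <- character(n_atoms)
  atom <- sprintf("A%d", seq_len(n_atoms) %% 1000L)
  for (k in seq_along(top$molecules)) {
    m <- top$molecules[[k]]
    resid[m$atoms] <- k
    resname[m$atoms] <- substr(m$species, 1, 5)
    atom[m$head] <- if (m$species %in% c("CHOL", "DMCHOL")) "O3" else "P"
  }
  resname[resname == ""] <- "MOL"
  resid[resid == 0L] <- 1L
  list(resid = resid, resname = resname, atom = atom)
}

xyz_sidecar_path <- function(path) paste0(path, ".box.json")

read_xyz <- function(path, dt = 1) {
  side <- xyz_sidecar_path(path)
  if (!file.exists(side))
    stop("XYZ input requires a box side-car file at ", side,
         ' (JSON: {"schema":1,"box_nm":[Lx,Ly,Lz]})')
  bx <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(bx$box_nm) || length(bx$box_nm) != 3L)
    stop("box side-car ", side, " must contain a length-3 box_nm field")
  lines <- readLines(path)
  frames <- list(); times <- numeric(); i <- 1L
  n_ref <- NA_integer_; fno <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop("parse error at line ", i, ": invalid atom count")
    fno <- fno + 1L
    if (is.na(n_ref)) n_ref <- nat
    else if (nat != n_ref)
      stop("structure error: frame ", fno, " has ", nat,
           " atoms, expected ", n_ref)
    if (i + 1L + nat > length(lines))
      stop("parse error at line ", length(lines), ": truncated frame")
    times[fno] <- parse_gro_time(lines[i + 1L])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    bad <- which(vapply(rows, length, 1L) < 4L)
    if (length(bad))
      stop("parse error at line ", i + 1L + bad[1], ": malformed XYZ record")
    co <- vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))
    if (any(is.na(co)))
      stop("parse error near line ", i + 2L, ": non-numeric coordinate")
    frames[[fno]] <- t(co) * NM_PER_ANGSTROM
    i <- i + 2L + nat
  }
  if (fno == 0L) stop("parse error: no frames found in ", path)
  if (any(is.na(times))) times <- (seq_len(fno) - 1) * dt
  new_trajectory(frames, times, bx$box_nm)
}

write_xyz <- function(traj, path, top = NULL) {
  con <- file(path, open = "wt")
  for (f in seq_len(n_frames(traj))) {
    p <- traj$positions[[f]] / NM_PER_ANGSTROM
    writeLines(sprintf("%d", traj$n_atoms), con)
    writeLines(sprintf("frame %d t= %.6f", f, traj$times[f]), con)
    writeLines(sprintf("C %12.6f %12.6f %12.6f", p[, 1], p[, 2], p[, 3]), con)
  }
  close(con)
  jsonlite::write_json(list(schema = 1L, box_nm = traj$box[1, ]),
                       xyz_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bilayer trajectory from GRO or XYZ
#'
#' GRO files are fixed-width, in nm, with the box on the last line of every
#' frame; a `t=` token in the title line is read as the frame time in ns.
#' XYZ files are assumed to be in Angstrom (converted to nm on read) and
#' require a side-car `<path>.box.json` with the orthorhombic box in nm.
#' Coordinates are returned exactly as stored (not wrapped).
#'
#' @param path Input file path.
#' @param format `"gro"` or `"xyz"`; inferred from the extension by default.
#' @param dt Frame spacing in ns, used when the file carries no time stamps.
#' @return A [new_trajectory()] object.
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "xyz"), dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "gro"
  switch(format, gro = read_gro(path, dt = dt), xyz = read_xyz(path, dt = dt))
}

#' Write a trajectory to GRO or XYZ
#'
#' @param traj A `bilayer_trajectory` (non-empty).
#' @param path Output path.
#' @param format `"gro"` or `"xyz"` (extension-inferred by default).
#' @param top Optional topology used to label residues in GRO output.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "gro", "xyz"),
                             top = NULL) {
  format <- match.arg(format)
  if (!inherits(traj, "bilayer_trajectory") || n_frames(traj) == 0L)
    stop("trajectory must be a non-empty bilayer_trajectory")
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "gro"
  ok <- tryCatch({
    switch(format, gro = write_gro(traj, path, top),
           xyz = write_xyz(traj, path, top)); TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

# Frame index whose time matches t (ns) within tolerance.
frame_at_time <- function(traj, t, tol = 1e-6) {
  i <- which(abs(traj$times - t) <= tol + 1e-9 * max(1, abs(t)))
  if (!length(i)) stop("sampling error: no frame at t = ", t, " ns")
  i[1]
}

#' In-plane displacement of one molecule over a time interval
#'
#' The molecule's reference point (DPPC: headgroup phosphorus; sterols:
#' ring-atom centroid) is tracked from `t0` to `t0 + dt` with per-frame
#' minimum-image continuation, so displacements across the periodic boundary
#' are true path displacements, not wrapped ones.
#'
#' @param traj A `bilayer_trajectory`.
#' @param top The matching topology.
#' @param molecule Molecule id (as in the topology).
#' @param t0 Start time, ns.
#' @param dt Interval, ns; must be a positive multiple of the frame spacing.
#' @return Lateral displacement |Delta(x, y)|, nm.
#' @export
lateral_displacement <- function(traj, top, molecule, t0, dt) {
  if (dt <= 0) stop("dt must be > 0")
  sp <- traj$spacing
  if (is.na(sp)) stop("sampling error: single-frame trajectory")
  if (abs(dt / sp - round(dt / sp)) > 1e-6)
    stop("sampling error: dt must be a multiple of the frame spacing (",
         sp, " ns)")
  i0 <- frame_at_time(traj, t0)
  i1 <- frame_at_time(traj, t0 + dt)
  xy <- reference_xy_series(traj, top, molecule, i0:i1)
  un <- unwrap_series(xy, traj$box[1, 1:2])
  sqrt(sum((un[nrow(un), ] - un[1, ])^2))
}

# Reference-point xy trace for one molecule over the given frames.
reference_xy_series <- function(traj, top, molecule, frames) {
  m <- topology_molecule(top, molecule)
  t(vapply(frames, function(f) {
    reference_point(traj$positions[[f]], m, traj$box[f, ])[1:2]
  }, numeric(2)))
}

# 3D reference point of a molecule record in one frame.
reference_point <- function(pos, m, box) {
  if (m$species %in% c("CHOL", "DMCHOL"))
    periodic_centroid(pos[m$ring_atoms, , drop = FALSE], box)
  else pos[m$head, ]
}

# Reference points of all molecules for one frame: n_mol x 3 matrix.
reference_points_frame <- function(traj, top, frame) {
  pos <- traj$positions[[frame]]; box <- traj$box[frame, ]
  t(vapply(top$molecules, function(m) reference_point(pos, m, box),
           numeric(3)))
}
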