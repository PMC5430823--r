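# Topology: explicit JSON side-car describing molecule species and atom
# roles. Force-field agnostic by design -- nothing is inferred from atom
# names. Indices are 1-based (R convention); schema version 1.
#
# Schema (JSON):
#   {
#     "schema": 1,
#     "n_atoms": <int>,
#     "molecules": [
#       {
#         "id": "<string>", "species": "DPPC"|"CHOL"|"DMCHOL"|"OTHER",
#         "atoms": [<int> ...],          # all atom indices of the molecule
#         "head": <int>,                 # P for DPPC, hydroxyl O for sterols
#         "chains": [                    # DPPC: exactly two; sterols: absent
#           {"label": "sn-1"|"sn-2",
#            "carbons": [<int> ...],                 # ordered, acyl C2...
#            "hydrogens": [[<int>, ...] ...]}        # per carbon, may be []
#         ],
#         "ring_atoms": [<int> ...],     # sterols only, non-empty
#         "methyl_marker": <int>         # sterols: atom on the rough beta face
#       }, ...
#     ]
#   }

SPECIES_LEVELS <- c("DPPC", "CHOL", "DMCHOL", "OTHER")

new_topology <- function(molecules, n_atoms) {
  top <- structure(list(molecules = molecules, n_atoms = as.integer(n_atoms)),
                   class = "bilayer_topology")
  validate_topology(top)
  top
}

#' Validate a topology against its declared particle count
#'
#' Checks index ranges, the two-chain invariant for DPPC, and the non-empty
#' sterol ring list. Called automatically by [load_topology()].
#'
#' @param top A `bilayer_topology`.
#' @return `top`, invisibly; errors name the offending molecule id.
#' @export
validate_topology <- function(top) {
  n <- top$n_atoms
  ids <- vapply(top$molecules, function(m) as.character(m$id), "")
  if (anyDuplicated(ids)) stop("validation error: duplicated molecule ids")
  for (m in top$molecules) {
    where <- paste0("molecule '", m$id, "'")
    if (!m$species %in% SPECIES_LEVELS)
      stop("validation error: ", where, ": unknown species '", m$species, "'")
    idx <- c(m$atoms, m$head, unlist(lapply(m$chains, function(ch)
      c(ch$carbons, unlist(ch$hydrogens)))), m$ring_atoms, m$methyl_marker)
    idx <- idx[!is.na(idx)]
    if (!length(m$atoms))
      stop("validation error: ", where, ": empty atom list")
    if (any(idx < 1L | idx > n))
      stop("validation error: ", where, ": atom index out of range 1..", n)
    if (m$species == "DPPC" && length(m$chains) != 2L)
      stop("validation error: ", where,
           ": DPPC records must have exactly two chains")
    if (m$species %in% c("CHOL", "DMCHOL") && length(m$ring_atoms) == 0L)
      stop("validation error: ", where,
           ": sterol records need a non-empty ring-atom list")
    for (ch in m$chains) {
      if (length(ch$hydrogens) && length(ch$hydrogens) != length(ch$carbons))
        stop("validation error: ", where,
             ": hydrogens list must align with carbons")
      if (is.unsorted(ch$carbons, strictly = FALSE) &&
          any(diff(order(ch$carbons)) == 0))
        stop("validation error: ", where, ": carbon list malformed")
    }
  }
  invisible(top)
}

#' Load a topology from its JSON side-car
#'
#' @param path Path to a schema-1 topology JSON file (see the package
#'   vignette for the schema), or a pre-parsed list.
#' @return A validated `bilayer_topology`.
#' @export
load_topology <- function(path) {
  js <- if (is.character(path)) jsonlite::read_json(path) else path
  if (is.null(js$schema) || js$schema != 1L)
    stop("validation error: topology schema field must be 1")
  if (is.null(js$n_atoms)) stop("validation error: n_atoms missing")
  mols <- lapply(js$molecules, function(m) {
    list(id = as.character(m$id),
         species = toupper(as.character(m$species)),
         atoms = as.integer(unlist(m$atoms)),
         head = as.integer(m$head),
         chains = lapply(m$chains %||% list(), function(ch) list(
           label = as.character(ch$label),
           carbons = as.integer(unlist(ch$carbons)),
           hydrogens = lapply(ch$hydrogens %||% list(),
                              function(h) as.integer(unlist(h))))),
         ring_atoms = as.integer(unlist(m$ring_atoms %||% integer())),
         methyl_marker = if (is.null(m$methyl_marker)) NA_integer_
                         else as.integer(m$methyl_marker))
  })
  new_topology(mols, js$n_atoms)
}

#' Write a topology to its JSON side-car format
#' @param top A `bilayer_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  js <- list(schema = 1L, n_atoms = top$n_atoms,
             molecules = lapply(top$molecules, function(m) {
               out <- list(id = m$id, species = m$species, atoms = m$atoms,
                           head = m$head)
               if (length(m$chains)) out$chains <- m$chains
               if (length(m$ring_atoms)) out$ring_atoms <- m$ring_atoms
               if (!is.na(m$methyl_marker %||% NA))
                 out$methyl_marker <- m$methyl_marker
               out
             }))
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.bilayer_topology <- function(x, ...) {
  sp <- table(vapply(x$molecules, function(m) m$species, ""))
  cat("<bilayer_topology> ", length(x$molecules), " molecules (",
      paste(names(sp), sp, sep = ":", collapse = ", "), "), ",
      x$n_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Tidy per-molecule summary of a topology
#' @param x A `bilayer_topology`.
#' @param ... Unused.
#' @return Tibble with `molecule`, `species`, `n_atoms`, `n_chains`, `head`.
#' @export
as_tibble.bilayer_topology <- function(x, ...) {
  tibble::tibble(
    molecule = vapply(x$molecules, function(m) m$id, ""),
    species = vapply(x$molecules, function(m) m$species, ""),
    n_atoms = vapply(x$molecules, function(m) length(m$atoms), 1L),
    n_chains = vapply(x$molecules, function(m) length(m$chains), 1L),
    head = vapply(x$molecules, function(m) m$head, 1L))
}

topology_ids <- function(top) vapply(top$molecules, function(m) m$id, "")

topology_species <- function(top)
  vapply(top$molecules, function(m) m$species, "")

topology_molecule <- function(top, id) {
  i <- match(id, topology_ids(top))
  if (is.na(i)) stop("unknown molecule id '", id, "'")
  top$molecules[[i]]
}

is_sterol <- function(species) species %in% c("CHOL", "DMCHOL")

# Long bond table for order-parameter work: one row per (molecule, chain,
# carbon, hydrogen). carbon_no follows sn-2 numbering: first listed acyl
# carbon is C2.
bond_table <- function(top, chain = "sn-2") {
  rows <- list()
  for (m in top$molecules) {
    if (m$species != "DPPC") next
    for (ch in m$chains) {
      if (!identical(chain, "both") && !identical(ch$label, chain)) next
      nh <- lengths(ch$hydrogens)
      if (!length(ch$hydrogens) || all(nh == 0L)) next
      for (k in seq_along(ch$carbons)) {
        hs <- ch$hydrogens[[k]]
        if (!length(hs)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          molecule = m$id, chain = ch$label, carbon = k + 1L,
          c_idx = ch$carbons[k], h_idx = hs)
      }
    }
  }
  if (!length(rows)) return(tibble::tibble(
    molecule = character(), chain = character(), carbon = integer(),
    c_idx = integer(), h_idx = integer()))
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
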