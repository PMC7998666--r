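#' Bundle one structure's complete record
#'
#' A snapshot ties together everything known about one stationary point:
#' geometry, QTAIM atomic properties, IQA pair interactions and
#' thermochemistry. Any component may be absent, but at least one must be
#' present, and the components must agree on the atom universe: pair-table
#' labels must exist in the atom table, and atom-table labels must exist in
#' the structure, whenever both sides are present.
#'
#' @param label snapshot label (e.g. `"3b"`).
#' @param structure optional `famsec_structure`.
#' @param atom_table optional `famsec_atoms`.
#' @param pair_table optional `famsec_pairs`.
#' @param thermo optional single-row `famsec_thermo`.
#' @return object of class `famsec_snapshot`.
#' @export
snapshot <- function(label, structure = NULL, atom_table = NULL,
                     pair_table = NULL, thermo = NULL) {
  if (is.null(structure) && is.null(atom_table) &&
      is.null(pair_table) && is.null(thermo)) {
    stop("snapshot needs at least one component", call. = FALSE)
  }
  if (!is.null(structure)) stopifnot(inherits(structure, "famsec_structure"))
  if (!is.null(atom_table)) stopifnot(inherits(atom_table, "famsec_atoms"))
  if (!is.null(pair_table)) stopifnot(inherits(pair_table, "famsec_pairs"))
  if (!is.null(thermo)) {
    stopifnot(inherits(thermo, "famsec_thermo"), nrow(thermo) == 1L)
  }
  if (!is.null(pair_table) && !is.null(atom_table)) {
    orphan <- setdiff(pair_atoms(pair_table), atom_table$label)
    if (length(orphan)) {
      stop(sprintf("pair table references atoms missing from atom table: %s",
                   paste(orphan, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(atom_table) && !is.null(structure)) {
    orphan <- setdiff(atom_table$label, atom_labels(structure))
    if (length(orphan)) {
      stop(sprintf("atom table references atoms missing from structure: %s",
                   paste(orphan, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(label = as.character(label), structure = structure,
                 atom_table = atom_table, pair_table = pair_table,
                 thermo = thermo),
            class = "famsec_snapshot")
}

#' @export
print.famsec_snapshot <- function(x, ...) {
  parts <- c(
    if (!is.null(x$structure)) sprintf("structure (%d atoms)", nrow(x$structure$atoms)),
    if (!is.null(x$atom_table)) sprintf("atom table (%d atoms)", nrow(x$atom_table)),
    if (!is.null(x$pair_table)) sprintf("pair table (%d pairs)", nrow(x$pair_table)),
    if (!is.null(x$thermo)) sprintf("thermo (T = %g K)", x$thermo$T[1L])
  )
  cat(sprintf("<famsec_snapshot> %s: %s\n", x$label, paste(parts, collapse = ", ")))
  invisible(x)
}

#' Atom universe of a snapshot
#'
#' The atom labels a snapshot knows about, preferring the structure, then the
#' atom table, then the pair table.
#'
#' @param snap a `famsec_snapshot`.
#' @return character vector of labels.
#' @export
snapshot_universe <- function(snap) {
  stopifnot(inherits(snap, "famsec_snapshot"))
  if (!is.null(snap$structure)) return(atom_labels(snap$structure))
  if (!is.null(snap$atom_table)) return(snap$atom_table$label)
  if (!is.null(snap$pair_table)) return(pair_atoms(snap$pair_table))
  character(0)
}
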