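#' Build a molecular structure
#'
#' A structure is an ordered atom list with 1-based serials and Cartesian
#' coordinates in Angstrom. Atom labels are `element + serial` ("Li27").
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinate vectors (Angstrom).
#' @param label structure label (free text), e.g. a snapshot name.
#' @param serial optional integer serials; default `1:n` (contiguous, the
#'   invariant for structures read from XYZ). Explicit serials may be any
#'   unique positive integers, so a partial structure can keep the parent
#'   system's numbering (e.g. just Li27, C28, N4 out of an adduct).
#' @return an object of class `famsec_structure`: a list with `label` and an
#'   `atoms` data.frame (`serial`, `element`, `x`, `y`, `z`, `atom`).
#' @examples
#' new_structure("Li", 0, 0, 0)
#' @export
new_structure <- function(element, x, y, z, label = "", serial = NULL) {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (is.null(serial)) {
    serial <- seq_len(n)
  } else {
    serial <- as.integer(serial)
    if (anyDuplicated(serial) || any(is.na(serial)) || any(serial < 1L)) {
      stop("serials must be unique positive integers", call. = FALSE)
    }
  }
  bad <- !is_element(element)
  if (any(bad)) {
    stop(sprintf("invalid element symbol(s): %s",
                 paste(unique(element[bad]), collapse = ", ")), call. = FALSE)
  }
  coords <- c(x, y, z)
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  atoms <- data.frame(serial = serial, element = element,
                      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                      atom = paste0(element, serial),
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(label = as.character(label), atoms = atoms),
            class = "famsec_structure")
}

#' @export
print.famsec_structure <- function(x, ...) {
  cat(sprintf("<famsec_structure> %s: %d atoms\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms)))
  print(utils::head(x$atoms, 10L))
  if (nrow(x$atoms) > 10L) cat(sprintf("... %d more atoms\n", nrow(x$atoms) - 10L))
  invisible(x)
}

#' Atom labels of a structure
#' @param structure a `famsec_structure`.
#' @return character vector, e.g. `c("N1", "C2", ...)`.
#' @export
atom_labels <- function(structure) {
  stopifnot(inherits(structure, "famsec_structure"))
  structure$atoms$atom
}

#' Read a standard XYZ file
#'
#' First line: atom count; second line: comment (kept as the structure label
#' when non-empty); then one `element x y z` record per atom. Serials are
#' assigned 1..N in file order.
#'
#' @param file path or connection.
#' @return a `famsec_structure`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ stream", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("XYZ line 1: atom count is not an integer", call. = FALSE)
  if (length(lines) < n + 2L) {
    stop(sprintf("XYZ count mismatch: header declares %d atoms but file has %d atom lines",
                 n, max(0L, length(lines) - 2L)), call. = FALSE)
  }
  comment <- if (length(lines) >= 2L) trimws(lines[2L]) else ""
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ line %d: expected 'element x y z'", ln), call. = FALSE)
    }
    el[i] <- tok[1L]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v))) {
      stop(sprintf("XYZ line %d: non-numeric coordinate", ln), call. = FALSE)
    }
    xyz[i, ] <- v
  }
  extra <- lines[-seq_len(n + 2L)]
  if (any(nzchar(trimws(extra)))) {
    stop(sprintf("XYZ count mismatch: header declares %d atoms but extra atom lines follow line %d",
                 n, n + 2L), call. = FALSE)
  }
  new_structure(el, xyz[, 1L], xyz[, 2L], xyz[, 3L], label = comment)
}

#' Write a standard XYZ file
#' @param structure a `famsec_structure`.
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(structure, file) {
  stopifnot(inherits(structure, "famsec_structure"))
  a <- structure$atoms
  lines <- c(
    as.character(nrow(a)),
    structure$label,
    sprintf("%-2s %18.10f %18.10f %18.10f", a$element, a$x, a$y, a$z)
  )
  writeLines(lines, file)
  invisible(file)
}
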