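#' Read a simplified AIMAll-style summary file
#'
#' Parses a documented, simplified dialect of the AIMAll `.sum` layout (not
#' the full vendor format): an atomic-properties section and an IQA pairwise
#' section, energies in hartree, converted to kcal/mol on read.
#'
#' The dialect is two sections with fixed headers, whitespace-delimited
#' records, blank lines and `#` comments ignored:
#'
#' ```
#' [Atomic Properties]
#' Atom   q(A)
#' Li27   0.9463
#' C28   -0.8
#'
#' [IQA Pairwise]
#' A      B      Vcl(A,B)    VXC(A,B)
#' Li27   C28    -0.14486    -0.02550
#' ```
#'
#' A file with only the atomic section yields an empty pair table; a missing
#' atomic section is a parse error.
#'
#' @param file path or connection.
#' @return list with elements `atoms` (a `famsec_atoms` table, charges in e)
#'   and `pairs` (a `famsec_pairs` table, kcal/mol).
#' @export
read_aimall_sum <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines_t <- trimws(lines)
  keep <- nzchar(lines_t) & !startsWith(lines_t, "#")
  idx <- which(keep)

  sec_atoms <- which(lines_t == "[Atomic Properties]")
  sec_pairs <- which(lines_t == "[IQA Pairwise]")
  if (length(sec_atoms) != 1L) {
    stop("missing or repeated section [Atomic Properties]", call. = FALSE)
  }
  if (length(sec_pairs) > 1L) {
    stop("repeated section [IQA Pairwise]", call. = FALSE)
  }

  section_lines <- function(start, end) {
    ln <- idx[idx > start & idx < end]
    ln[!lines_t[ln] %in% c("[Atomic Properties]", "[IQA Pairwise]")]
  }
  end_atoms <- if (length(sec_pairs) && sec_pairs > sec_atoms) sec_pairs
               else length(lines) + 1L
  at_ln <- section_lines(sec_atoms, end_atoms)

  parse_rows <- function(ln, ncol, header, section) {
    if (!length(ln)) {
      stop(sprintf("section %s: missing header line", section), call. = FALSE)
    }
    head_tok <- strsplit(lines_t[ln[1L]], "[[:space:]]+")[[1L]]
    if (!identical(head_tok, header)) {
      stop(sprintf("section %s line %d: expected header '%s'",
                   section, ln[1L], paste(header, collapse = " ")),
           call. = FALSE)
    }
    rows <- lapply(ln[-1L], function(i) {
      tok <- strsplit(lines_t[i], "[[:space:]]+")[[1L]]
      if (length(tok) != ncol) {
        stop(sprintf("section %s line %d: expected %d fields, got %d",
                     section, i, ncol, length(tok)), call. = FALSE)
      }
      tok
    })
    rows
  }

  at_rows <- parse_rows(at_ln, 2L, c("Atom", "q(A)"), "[Atomic Properties]")
  at_lab <- vapply(at_rows, `[[`, "", 1L)
  at_q <- suppressWarnings(as.numeric(vapply(at_rows, `[[`, "", 2L)))
  if (any(is.na(at_q))) {
    stop(sprintf("section [Atomic Properties]: non-numeric charge for %s",
                 paste(at_lab[is.na(at_q)], collapse = ", ")), call. = FALSE)
  }
  atoms <- new_atom_table(at_lab, at_q)

  if (!length(sec_pairs)) {
    return(list(atoms = atoms, pairs = new_pair_table()))
  }
  pr_ln <- section_lines(sec_pairs, length(lines) + 1L)
  pr_rows <- parse_rows(pr_ln, 4L, c("A", "B", "Vcl(A,B)", "VXC(A,B)"),
                        "[IQA Pairwise]")
  if (!length(pr_rows)) {
    return(list(atoms = atoms, pairs = new_pair_table()))
  }
  a <- vapply(pr_rows, `[[`, "", 1L)
  b <- vapply(pr_rows, `[[`, "", 2L)
  vcl <- suppressWarnings(as.numeric(vapply(pr_rows, `[[`, "", 3L)))
  vxc <- suppressWarnings(as.numeric(vapply(pr_rows, `[[`, "", 4L)))
  if (any(is.na(vcl) | is.na(vxc))) {
    bad <- which(is.na(vcl) | is.na(vxc))[1L]
    stop(sprintf("section [IQA Pairwise] line %d: non-numeric energy",
                 pr_ln[-1L][bad]), call. = FALSE)
  }
  pairs <- new_pair_table(a, b,
                          convert_units(vcl, "hartree", "kcal/mol"),
                          convert_units(vxc, "hartree", "kcal/mol"))
  missing_atoms <- setdiff(pair_atoms(pairs), atoms$label)
  if (length(missing_atoms)) {
    stop(sprintf("pairwise section references atoms absent from [Atomic Properties]: %s",
                 paste(missing_atoms, collapse = ", ")), call. = FALSE)
  }
  list(atoms = atoms, pairs = pairs)
}
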