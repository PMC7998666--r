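#' Build an atomic property table
#'
#' Holds QTAIM net atomic charges Q(A) in e and, optionally, IQA atomic
#' self-energies in kcal/mol, keyed by atom label.
#'
#' @param label atom labels ("N1", "Li27").
#' @param Q net atomic charges (e).
#' @param E_self optional atomic self-energies (kcal/mol); NA when absent.
#' @return object of class `famsec_atoms` (a data.frame with columns
#'   `label`, `element`, `Q`, `E_self`).
#' @examples
#' new_atom_table(c("N1", "Li27"), c(-1.1164, 0.9463))
#' @export
new_atom_table <- function(label, Q, E_self = NULL) {
  label <- as.character(label)
  if (anyDuplicated(label)) {
    stop(sprintf("duplicate atom label(s): %s",
                 paste(unique(label[duplicated(label)]), collapse = ", ")),
         call. = FALSE)
  }
  el <- if (length(label)) split_atom_label(label)$element else character(0)
  if (is.null(E_self)) E_self <- rep(NA_real_, length(label))
  out <- data.frame(label = label, element = el, Q = as.numeric(Q),
                    E_self = as.numeric(E_self), stringsAsFactors = FALSE)
  class(out) <- c("famsec_atoms", "data.frame")
  out
}

#' Read an atomic property table (CSV)
#'
#' Native format: comma-delimited UTF-8 with header `label,element,Q` and
#' optional `E_self` column; charges in e, self-energies in kcal/mol.
#'
#' @param file path or connection.
#' @return a `famsec_atoms` table.
#' @export
read_atom_table <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("label", "element", "Q")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop(sprintf("atom table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(d) == 0L) return(new_atom_table(character(0), numeric(0)))
  tab <- new_atom_table(d$label, d$Q,
                        if ("E_self" %in% names(d)) d$E_self else NULL)
  # declared element column must agree with the label's element prefix
  bad <- d$element != tab$element
  if (any(bad)) {
    stop(sprintf("element column disagrees with label prefix for: %s",
                 paste(d$label[bad], collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Write an atomic property table (CSV)
#' @param atoms a `famsec_atoms` table.
#' @param file path or connection.
#' @export
write_atom_table <- function(atoms, file) {
  stopifnot(inherits(atoms, "famsec_atoms"))
  utils::write.csv(as.data.frame(atoms), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Build an IQA pair interaction table
#'
#' Maps unordered atom pairs \{A,B\} to the classical (`Vcl`) and
#' exchange-correlation (`VXC`) components of the IQA pairwise interaction
#' energy, in kcal/mol. Pairs are stored once, canonically ordered
#' (lexicographic by element symbol, then serial), and looked up
#' symmetrically: `pair_lookup(pt, A, B)` and `pair_lookup(pt, B, A)` return
#' the identical record.
#'
#' @param a,b atom-label vectors defining the pairs.
#' @param Vcl,VXC energy components (kcal/mol).
#' @return object of class `famsec_pairs` (data.frame `a`, `b`, `Vcl`, `VXC`).
#' @examples
#' new_pair_table("Li27", "C28", -90.9, -16.0)
#' @export
new_pair_table <- function(a = character(0), b = character(0),
                           Vcl = numeric(0), VXC = numeric(0)) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b), length(Vcl) == length(a),
            length(VXC) == length(a))
  if (any(a == b)) {
    stop(sprintf("self-pair(s) not allowed: %s",
                 paste(unique(a[a == b]), collapse = ", ")), call. = FALSE)
  }
  if (length(a)) {
    cp <- canonical_pair(a, b)
    a <- cp$a; b <- cp$b
  }
  key <- paste(a, b, sep = "|")
  if (anyDuplicated(key)) {
    # duplicates with identical values are deduplicated; conflicts error
    first <- !duplicated(key)
    idx <- match(key, key[first])
    conflict <- abs(Vcl - Vcl[first][idx]) > 1e-12 |
      abs(VXC - VXC[first][idx]) > 1e-12
    if (any(conflict)) {
      stop(sprintf("conflicting duplicate pair(s): %s",
                   paste(unique(paste0("{", a[conflict], ",", b[conflict], "}")),
                         collapse = ", ")), call. = FALSE)
    }
    a <- a[first]; b <- b[first]; Vcl <- Vcl[first]; VXC <- VXC[first]
  }
  out <- data.frame(a = a, b = b, Vcl = as.numeric(Vcl), VXC = as.numeric(VXC),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    pa <- split_atom_label(out$a); pb <- split_atom_label(out$b)
    out <- out[order(pa$element, pa$serial, pb$element, pb$serial), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("famsec_pairs", "data.frame")
  out
}

#' Look up one pair record, symmetric in its arguments
#'
#' @param pairs a `famsec_pairs` table.
#' @param a,b atom labels.
#' @param strict error (rather than return `NULL`) when the pair is absent.
#' @return list with `a`, `b` (canonical order), `Vcl`, `VXC`, or `NULL`.
#' @export
pair_lookup <- function(pairs, a, b, strict = FALSE) {
  stopifnot(inherits(pairs, "famsec_pairs"), length(a) == 1L, length(b) == 1L)
  cp <- canonical_pair(a, b)
  hit <- which(pairs$a == cp$a & pairs$b == cp$b)
  if (!length(hit)) {
    if (strict) {
      stop(sprintf("pair {%s,%s} absent from pair table", cp$a, cp$b),
           call. = FALSE)
    }
    return(NULL)
  }
  as.list(pairs[hit[1L], c("a", "b", "Vcl", "VXC")])
}

#' Read an IQA pair table (CSV)
#'
#' Native format: comma-delimited with header `A,B,Vcl,VXC`. Energies are
#' converted to kcal/mol on read. Listing the same unordered pair twice with
#' equal values is deduplicated; with different values it is an error.
#'
#' @param file path or connection.
#' @param units input energy unit, `"kcal/mol"` (default) or `"hartree"`.
#' @return a `famsec_pairs` table in kcal/mol.
#' @export
read_pair_table <- function(file, units = "kcal/mol") {
  units <- match_unit(units)
  if (units == "kJ/mol") {
    stop("unknown unit for pair tables: use kcal/mol or hartree", call. = FALSE)
  }
  d <- utils::read.csv(file, stringsAsFactors = FALSE, strip.white = TRUE)
  names(d) <- sub("^A$", "a", sub("^B$", "b", names(d)))
  req <- c("a", "b", "Vcl", "VXC")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop(sprintf("pair table missing column(s): %s",
                 paste(toupper(miss), collapse = ", ")), call. = FALSE)
  }
  new_pair_table(as.character(d$a), as.character(d$b),
                 convert_units(as.numeric(d$Vcl), units, "kcal/mol"),
                 convert_units(as.numeric(d$VXC), units, "kcal/mol"))
}

#' Write an IQA pair table (CSV, kcal/mol)
#' @param pairs a `famsec_pairs` table.
#' @param file path or connection.
#' @export
write_pair_table <- function(pairs, file) {
  stopifnot(inherits(pairs, "famsec_pairs"))
  d <- as.data.frame(pairs)
  names(d)[1:2] <- c("A", "B")
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Atom labels appearing in a pair table
#' @param pairs a `famsec_pairs` table.
#' @export
pair_atoms <- function(pairs) {
  stopifnot(inherits(pairs, "famsec_pairs"))
  sort_labels(unique(c(pairs$a, pairs$b)))
}
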