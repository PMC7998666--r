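#' Molecular fragments: named atom-label sets
#'
#' A fragment is a named set of atom labels within a snapshot's atom
#' universe. Fragments are the unit of attribution for all energy sums.
#'
#' @param name fragment name (ASCII; a display alias may differ).
#' @param members character vector of atom labels.
#' @param display optional display name (e.g. a script-letter alias).
#' @return object of class `famsec_fragment`.
#' @export
fragment <- function(name, members, display = name) {
  members <- unique(as.character(members))
  split_atom_label(members)  # validates
  structure(list(name = as.character(name), members = sort_labels(members),
                 display = as.character(display)),
            class = "famsec_fragment")
}

#' @export
print.famsec_fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s = {%s}\n", x$name, paste(x$members, collapse = ",")))
  invisible(x)
}

#' @export
format.famsec_fragment <- function(x, ...) {
  paste(x$members, collapse = ",")
}

#' Parse a fragment specification string
#'
#' The spec grammar is a comma-separated list of atom labels and serial
#' ranges `Xi-Yj`, where a range spans all serials `i..j` inclusive
#' *regardless of element*: `"N1-H15"` over a quinoxaline universe expands to
#' the 15 atoms with serials 1 to 15. Range endpoints must exist in the
#' universe.
#'
#' @param text spec string, e.g. `"C5-C10,H12-H15"` or `"C2,C3,C5,C10"`.
#' @param universe character vector of all atom labels in scope (supplies the
#'   serial-to-label mapping).
#' @param name fragment name; defaults to the spec string itself.
#' @param display optional display alias.
#' @return a `famsec_fragment`.
#' @examples
#' u <- quinoxaline_universe()
#' parse_fragment_spec("N1-H15", u, name = "Q")
#' @export
parse_fragment_spec <- function(text, universe, name = text, display = name) {
  stopifnot(is.character(text), length(text) == 1L)
  up <- split_atom_label(universe)
  if (anyDuplicated(up$serial)) {
    stop("universe has duplicate serials; ranges are ambiguous", call. = FALSE)
  }
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty fragment spec", call. = FALSE)
  members <- character(0)
  for (tok in tokens) {
    if (grepl("-", tok, fixed = TRUE)) {
      ends <- trimws(strsplit(tok, "-", fixed = TRUE)[[1L]])
      if (length(ends) != 2L) {
        stop(sprintf("malformed range '%s'", tok), call. = FALSE)
      }
      ep <- split_atom_label(ends)
      for (k in 1:2) {
        if (!ends[k] %in% universe) {
          stop(sprintf("range endpoint '%s' not in universe", ends[k]),
               call. = FALSE)
        }
      }
      if (ep$serial[1L] > ep$serial[2L]) {
        stop(sprintf("reversed range '%s' (%d > %d)", tok,
                     ep$serial[1L], ep$serial[2L]), call. = FALSE)
      }
      members <- c(members,
                   universe[up$serial >= ep$serial[1L] &
                            up$serial <= ep$serial[2L]])
    } else {
      if (!tok %in% universe) {
        stop(sprintf("atom label '%s' not in universe", tok), call. = FALSE)
      }
      members <- c(members, tok)
    }
  }
  fragment(name, members, display = display)
}

#' Build a named fragment set
#'
#' @param ... `famsec_fragment` objects, or a single list of them.
#' @param universe optional declared universe (atom labels) the fragments
#'   must stay within.
#' @return object of class `famsec_fragset` (a named list of fragments with a
#'   `universe` attribute).
#' @export
fragment_set <- function(..., universe = NULL) {
  frags <- list(...)
  if (length(frags) == 1L && !inherits(frags[[1L]], "famsec_fragment") &&
      is.list(frags[[1L]])) {
    frags <- frags[[1L]]
  }
  ok <- vapply(frags, inherits, TRUE, "famsec_fragment")
  if (!all(ok)) stop("all elements must be famsec_fragment objects", call. = FALSE)
  nm <- vapply(frags, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate fragment name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  names(frags) <- nm
  if (!is.null(universe)) {
    for (f in frags) {
      stray <- setdiff(f$members, universe)
      if (length(stray)) {
        stop(sprintf("fragment %s has members outside the declared universe: %s",
                     f$name, paste(stray, collapse = ", ")), call. = FALSE)
      }
    }
  }
  structure(frags, universe = universe, class = "famsec_fragset")
}

#' @export
print.famsec_fragset <- function(x, ...) {
  cat(sprintf("<famsec_fragset> %d fragments\n", length(x)))
  for (f in x) cat(sprintf("  %-4s = {%s}\n", f$name, paste(f$members, collapse = ",")))
  invisible(x)
}

#' @export
`[[.famsec_fragset` <- function(x, i) {
  NextMethod()
}

#' Validate a fragment set against a snapshot or universe
#'
#' Modes: `"disjoint"` requires pairwise-disjoint fragments; `"partition"`
#' additionally requires every universe atom to be covered; `"none"` only
#' checks membership in the universe. Returns a report rather than erroring.
#'
#' @param fset a `famsec_fragset`.
#' @param universe character vector of atom labels, or a `famsec_snapshot`
#'   (its universe is used).
#' @param mode one of `"disjoint"`, `"partition"`, `"none"`.
#' @return list with `ok` (logical), `overlaps` (data.frame `fragment_a`,
#'   `fragment_b`, `shared`), `uncovered` (labels, partition mode),
#'   `unknown` (labels outside the universe).
#' @export
validate_fragments <- function(fset, universe, mode = c("disjoint", "partition", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fset, "famsec_fragset"))
  if (inherits(universe, "famsec_snapshot")) universe <- snapshot_universe(universe)
  unknown <- character(0)
  for (f in fset) unknown <- union(unknown, setdiff(f$members, universe))
  overlaps <- data.frame(fragment_a = character(0), fragment_b = character(0),
                         shared = character(0), stringsAsFactors = FALSE)
  if (mode %in% c("disjoint", "partition") && length(fset) > 1L) {
    nm <- names(fset)
    for (i in seq_len(length(fset) - 1L)) {
      for (j in seq(i + 1L, length(fset))) {
        shared <- intersect(fset[[i]]$members, fset[[j]]$members)
        if (length(shared)) {
          overlaps <- rbind(overlaps, data.frame(
            fragment_a = nm[i], fragment_b = nm[j],
            shared = paste(sort_labels(shared), collapse = ","),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  uncovered <- character(0)
  if (mode == "partition") {
    covered <- unique(unlist(lapply(fset, `[[`, "members")))
    uncovered <- sort_labels(setdiff(universe, covered))
  }
  ok <- length(unknown) == 0L &&
    (mode == "none" || nrow(overlaps) == 0L) &&
    (mode != "partition" || length(uncovered) == 0L)
  list(ok = ok, mode = mode, overlaps = overlaps,
       uncovered = uncovered, unknown = sort_labels(unknown))
}

#' Atom universe of the quinoxaline + lithium phenylacetylide system
#'
#' Labels for 2-phenylquinoxaline (serials 1-26: the quinoxaline core N1-H15
#' and the phenyl substituent C16-H26) and lithium phenylacetylide
#' (Li27, the acetylide carbons C28-C29 and the phenyl ring C30-H40), plus
#' the water molecule (O41, H42, H43) when `with_water = TRUE`.
#'
#' @param with_water include the water atoms used in the hydrolysis stage.
#' @return character vector of atom labels in serial order.
#' @export
quinoxaline_universe <- function(with_water = FALSE) {
  el <- c("N", "C", "C", "N", rep("C", 6),          # N1 C2 C3 N4 C5-C10
          rep("H", 5),                              # H11-H15
          rep("C", 6), rep("H", 5),                 # phenyl at C2: C16-C21, H22-H26
          "Li", "C", "C",                           # Li27 C28 C29
          rep("C", 6), rep("H", 5))                 # phenyl of 2: C30-C35, H36-H40
  if (with_water) el <- c(el, "O", "H", "H")
  paste0(el, seq_along(el))
}

#' Fragment library for the 2-phenylquinoxaline + lithium phenylacetylide
#' ONSH study system
#'
#' The sixteen named fragments used in fragment-attributed analysis of the
#' nucleophilic-addition stage, expanded to explicit label sets:
#'
#' * `Q` (quinoxaline moiety) = N1-H15; `Ph1` (phenyl at C2) = C16-H26
#' * `Bn` (benzene ring) = C5-C10, H12-H15; `P` (pyrazine ring) = N1, C2, C3,
#'   N4, C5, C10, H11
#' * `N` = \{N1, N4\} (nucleophilic N atoms); `C` = \{C2, C3, C5, C10\}
#'   (electrophilic C atoms)
#' * `L` = \{Li27, C28, C29\}; `A` = \{C28, C29\}; `R` = C28-H40 (molecule 2
#'   without Li); `Ph2` = C30-H40
#' * three-atom N environments `G1` = \{C2, N1, C10\}, `G2` = \{C3, N4, C5\};
#'   four-atom C environments `F1`-`F4`
#'
#' Script-letter display aliases are attached to each fragment.
#'
#' @return a `famsec_fragset` over [quinoxaline_universe()].
#' @export
quinoxaline_fragment_library <- function() {
  u <- quinoxaline_universe()
  f <- function(name, spec, display) parse_fragment_spec(spec, u, name, display)
  fragment_set(
    f("Q",   "N1-H15",          "\U0001D4AC"),
    f("Ph1", "C16-H26",         "\U0001D4AB\U0001D4BD1"),
    f("Bn",  "C5-C10,H12-H15",  "\U0001D4D1\U0001D4C3"),
    f("P",   "N1,C2,C3,N4,C5,C10,H11", "\U0001D4AB"),
    f("N",   "N1,N4",           "\U0001D4DD"),
    f("C",   "C2,C3,C5,C10",    "\U0001D4D2"),
    f("L",   "Li27,C28,C29",    "\U0001D4DB"),
    f("A",   "C28,C29",         "\U0001D4D0"),
    f("R",   "C28-H40",         "\U0001D4E1"),
    f("Ph2", "C30-H40",         "\U0001D4AB\U0001D4BD2"),
    f("G1",  "C2,N1,C10",       "\U0001D4A21"),
    f("G2",  "C3,N4,C5",        "\U0001D4A22"),
    f("F1",  "N1,C2,C3,C16",    "ℱ1"),
    f("F2",  "C2,C3,N4,H11",    "ℱ2"),
    f("F3",  "N4,C5,C6,C10",    "ℱ3"),
    f("F4",  "C5,C10,C9,N1",    "ℱ4"),
    universe = u
  )
}

#' Read a fragment set from a YAML file
#'
#' Layout: an optional `universe` key (a spec string or list of labels over
#' which ranges are resolved) and a `fragments` mapping of name to spec
#' string. Without a `universe` key the quinoxaline universe (with water) is
#' assumed.
#'
#' @param file path to YAML.
#' @return a `famsec_fragset`.
#' @export
read_fragments_yaml <- function(file) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$fragments) || !length(doc$fragments)) {
    stop("fragments.yaml must contain a non-empty 'fragments' mapping",
         call. = FALSE)
  }
  # unquoted single-letter YAML keys like N or Y parse as booleans
  if (any(names(doc$fragments) %in% c("TRUE", "FALSE"))) {
    stop("fragment name parsed as a YAML boolean; quote names like \"N\" or \"Y\"",
         call. = FALSE)
  }
  universe <- if (!is.null(doc$universe)) {
    unlist(doc$universe, use.names = FALSE)
  } else {
    quinoxaline_universe(with_water = TRUE)
  }
  frags <- lapply(names(doc$fragments), function(nm) {
    parse_fragment_spec(as.character(doc$fragments[[nm]]), universe, name = nm)
  })
  fragment_set(frags, universe = universe)
}
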