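#' Total interaction energy of one atom pair
#'
#' The IQA pairwise interaction energy is the sum of its classical
#' (coulombic) and exchange-correlation (covalent) components:
#' `V(A,B) = Vcl(A,B) + VXC(A,B)`.
#'
#' @param pair a pair record: a list (or single-row data.frame) with numeric
#'   `Vcl` and `VXC` in kcal/mol, e.g. from [pair_lookup()].
#' @return total interaction energy, kcal/mol.
#' @examples
#' pair_total(list(Vcl = -90.9, VXC = -16.0))  # -106.9
#' @export
pair_total <- function(pair) {
  v <- as.numeric(pair$Vcl) + as.numeric(pair$VXC)
  if (!all(is.finite(v))) stop("pair components must be finite", call. = FALSE)
  v
}

#' Interfragment interaction energy
#'
#' Sums the requested IQA component over every unordered atom pair with one
#' member in each fragment. Pairs absent from the table contribute exactly
#' zero and are excluded from `n_pairs_counted` (set `strict = TRUE` to make
#' absence an error instead). Each unordered pair is counted once; no
#' halving, no double counting, so interfragment sums over a partition plus
#' the intra-fragment sums reproduce the full-table sum exactly.
#'
#' @param pairs a `famsec_pairs` table (kcal/mol).
#' @param frag_a,frag_b disjoint `famsec_fragment` objects (or plain label
#'   vectors).
#' @param term which component to report as `value`: `"total"`, `"cl"`, `"xc"`.
#' @param strict error when any cross pair is missing from the table.
#' @return object of class `famsec_interaction`: list with `fragment_a`,
#'   `fragment_b`, `Vcl_sum`, `VXC_sum`, `V_total`, `value`, `term`,
#'   `n_pairs_counted`, `n_pairs_possible`.
#' @export
interfragment_energy <- function(pairs, frag_a, frag_b,
                                 term = c("total", "cl", "xc"),
                                 strict = FALSE) {
  term <- match.arg(term)
  stopifnot(inherits(pairs, "famsec_pairs"))
  fa <- as_members(frag_a); fb <- as_members(frag_b)
  shared <- intersect(fa$members, fb$members)
  if (length(shared)) {
    stop(sprintf("fragments %s and %s overlap on: %s", fa$name, fb$name,
                 paste(sort_labels(shared), collapse = ", ")), call. = FALSE)
  }
  cross <- (pairs$a %in% fa$members & pairs$b %in% fb$members) |
           (pairs$a %in% fb$members & pairs$b %in% fa$members)
  n_possible <- length(fa$members) * length(fb$members)
  n_counted <- sum(cross)
  if (strict && n_counted < n_possible) {
    stop(sprintf("strict mode: %d of %d cross pairs between %s and %s absent from pair table",
                 n_possible - n_counted, n_possible, fa$name, fb$name),
         call. = FALSE)
  }
  vcl <- sum(pairs$Vcl[cross])
  vxc <- sum(pairs$VXC[cross])
  vtot <- vcl + vxc
  value <- switch(term, total = vtot, cl = vcl, xc = vxc)
  structure(list(fragment_a = fa$name, fragment_b = fb$name,
                 Vcl_sum = vcl, VXC_sum = vxc, V_total = vtot,
                 term = term, value = value,
                 n_pairs_counted = n_counted, n_pairs_possible = n_possible),
            class = "famsec_interaction")
}

#' @export
print.famsec_interaction <- function(x, ...) {
  cat(sprintf("E_int(%s, %s): Vcl %.1f  VXC %.1f  total %.1f kcal/mol (%d/%d pairs)\n",
              x$fragment_a, x$fragment_b, x$Vcl_sum, x$VXC_sum, x$V_total,
              x$n_pairs_counted, x$n_pairs_possible))
  invisible(x)
}

# Accept a famsec_fragment or a bare label vector.
as_members <- function(frag) {
  if (inherits(frag, "famsec_fragment")) {
    list(name = frag$name, members = frag$members)
  } else {
    members <- unique(as.character(frag))
    list(name = paste(members, collapse = ","), members = members)
  }
}

#' Intra-fragment interaction sum
#'
#' Sums one IQA component over all unordered pairs with *both* members inside
#' the fragment that appear in the pair table. With `term = "xc"` this is the
#' summed covalent interaction energy of a ring or moiety, the quantity whose
#' step-to-step change diagnoses loss of aromatic stabilisation at a
#' transition state.
#'
#' @param pairs a `famsec_pairs` table (kcal/mol).
#' @param frag a `famsec_fragment` (or label vector) with at least 2 members.
#' @param term `"total"`, `"cl"` or `"xc"`.
#' @return summed energy, kcal/mol.
#' @export
intrafragment_sum <- function(pairs, frag, term = c("total", "cl", "xc")) {
  term <- match.arg(term)
  stopifnot(inherits(pairs, "famsec_pairs"))
  f <- as_members(frag)
  if (length(f$members) < 2L) {
    stop(sprintf("fragment %s has fewer than 2 members; no internal pairs exist",
                 f$name), call. = FALSE)
  }
  inside <- pairs$a %in% f$members & pairs$b %in% f$members
  switch(term,
         total = sum(pairs$Vcl[inside]) + sum(pairs$VXC[inside]),
         cl = sum(pairs$Vcl[inside]),
         xc = sum(pairs$VXC[inside]))
}

#' Classical / exchange-correlation character of an interaction
#'
#' Expresses the two IQA components as percentages of the total:
#' `(100 * Vcl / V, 100 * VXC / V)`. The components always re-sum to 100
#' before rounding. A Li-C acetylide bond with (Vcl, VXC) =
#' (-90.9, -16.0) kcal/mol is 85% classical / 15% covalent.
#'
#' @param x a pair record (list with `Vcl`, `VXC`) or a
#'   `famsec_interaction` result.
#' @return named numeric `c(cl = ..., xc = ...)` in percent.
#' @export
percent_character <- function(x) {
  if (inherits(x, "famsec_interaction")) {
    vcl <- x$Vcl_sum; vxc <- x$VXC_sum
  } else {
    vcl <- as.numeric(x$Vcl); vxc <- as.numeric(x$VXC)
  }
  v <- vcl + vxc
  if (v == 0) {
    stop("percent character undefined: total interaction energy is zero",
         call. = FALSE)
  }
  c(cl = 100 * vcl / v, xc = 100 * vxc / v)
}

#' Net charge of a fragment
#'
#' Sum of QTAIM net atomic charges Q(A) over the fragment members.
#'
#' @param atoms a `famsec_atoms` table.
#' @param frag a `famsec_fragment` or label vector.
#' @return charge in e.
#' @export
fragment_charge <- function(atoms, frag) {
  stopifnot(inherits(atoms, "famsec_atoms"))
  f <- as_members(frag)
  hit <- match(f$members, atoms$label)
  if (anyNA(hit)) {
    stop(sprintf("fragment %s member(s) missing from atom table: %s",
                 f$name, paste(f$members[is.na(hit)], collapse = ", ")),
         call. = FALSE)
  }
  sum(atoms$Q[hit])
}

#' Rank pairwise interactions by total energy
#'
#' Returns the `k` strongest attractive (most negative total, ascending) or
#' repulsive (most positive, descending) atom pairs. With `split` given as a
#' pair of fragments, only pairs crossing the split are ranked. Ties are
#' broken by canonical pair ordering.
#'
#' @param pairs a `famsec_pairs` table.
#' @param k number of pairs to return (positive).
#' @param sense `"attractive"` or `"repulsive"`.
#' @param split optional list of two fragments (or label vectors); only
#'   pairs with one atom in each are considered.
#' @return data.frame `a`, `b`, `Vcl`, `VXC`, `total`, strongest first.
#' @export
rank_interactions <- function(pairs, k, sense = c("attractive", "repulsive"),
                              split = NULL) {
  sense <- match.arg(sense)
  stopifnot(inherits(pairs, "famsec_pairs"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive integer", call. = FALSE)
  }
  d <- as.data.frame(pairs)
  if (!is.null(split)) {
    stopifnot(length(split) == 2L)
    fa <- as_members(split[[1L]]); fb <- as_members(split[[2L]])
    keep <- (d$a %in% fa$members & d$b %in% fb$members) |
            (d$a %in% fb$members & d$b %in% fa$members)
    d <- d[keep, , drop = FALSE]
  }
  d$total <- d$Vcl + d$VXC
  if (!nrow(d)) return(d)
  # pairs table is already in canonical order, so stable sort breaks ties
  # canonically
  ord <- order(if (sense == "attractive") d$total else -d$total)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, as.integer(k))
}
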