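coords_of <- function(structure, label) {
  stopifnot(inherits(structure, "famsec_structure"))
  hit <- match(label, structure$atoms$atom)
  if (anyNA(hit)) {
    stop(sprintf("atom label(s) not in structure '%s': %s", structure$label,
                 paste(label[is.na(hit)], collapse = ", ")), call. = FALSE)
  }
  as.matrix(structure$atoms[hit, c("x", "y", "z"), drop = FALSE])
}

#' Internuclear distance
#'
#' @param structure a `famsec_structure`.
#' @param label_a,label_b atom labels.
#' @return Euclidean distance, Angstrom.
#' @export
atom_distance <- function(structure, label_a, label_b) {
  p <- coords_of(structure, c(label_a, label_b))
  sqrt(sum((p[2L, ] - p[1L, ])^2))
}

#' Signed dihedral (torsion) angle
#'
#' Torsion a-b-c-d by the IUPAC right-hand convention, in degrees in
#' (-180, 180]. Any three consecutive collinear atoms make the torsion
#' undefined and raise an error (cross-product norm below `1e-10` squared
#' Angstrom).
#'
#' @param structure a `famsec_structure`.
#' @param a,b,c,d four distinct atom labels.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(structure, a, b, c, d) {
  labs <- c(a, b, c, d)
  if (anyDuplicated(labs)) {
    stop("dihedral needs four distinct atoms", call. = FALSE)
  }
  p <- coords_of(structure, labs)
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("degenerate geometry: three consecutive atoms are collinear",
         call. = FALSE)
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  # right-hand (IUPAC) sign: positive when the far bond is rotated clockwise
  # from the near bond viewed from b towards c; invariant under a,b,c,d
  # reversal
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Bondi van der Waals radii
#'
#' The Bondi (1964) radii for the elements this toolkit commonly meets, in
#' Angstrom. Swap in another table by passing any named numeric vector of
#' radii to [vdw_contact()].
#'
#' @return named numeric vector, element symbol to radius (Angstrom).
#' @export
bondi_radii <- function() {
  c(H = 1.20, He = 1.40, Li = 1.81, Be = 1.53, B = 1.92, C = 1.70,
    N = 1.55, O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73,
    Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75,
    Br = 1.85, I = 1.98)
}

#' Classify a van der Waals contact
#'
#' An interatomic contact exists when the distance is *strictly* smaller
#' than the sum of the two van der Waals radii. The margin
#' `(r_a + r_b) - d` says how deeply the electron clouds interpenetrate;
#' at `d` exactly equal to the radii sum the margin is 0 and there is no
#' contact.
#'
#' @param structure a `famsec_structure`.
#' @param label_a,label_b atom labels.
#' @param radii named numeric vector of radii (Angstrom) by element;
#'   default [bondi_radii()].
#' @return list with `contact` (logical), `margin` (Angstrom), `distance`,
#'   `radii_sum`.
#' @export
vdw_contact <- function(structure, label_a, label_b, radii = bondi_radii()) {
  el <- split_atom_label(c(label_a, label_b))$element
  miss <- setdiff(el, names(radii))
  if (length(miss)) {
    stop(sprintf("no van der Waals radius for element(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d <- atom_distance(structure, label_a, label_b)
  rsum <- unname(radii[el[1L]] + radii[el[2L]])
  list(contact = d < rsum, margin = rsum - d, distance = d, radii_sum = rsum)
}

#' Geometry change report between two snapshots
#'
#' Tabulates distances and dihedrals in both structures with their change,
#' the bookkeeping behind statements like "the C2-C3 bond elongated from
#' 1.43 to 1.50 Angstrom at the transition state".
#'
#' @param snap_1,snap_2 `famsec_snapshot` objects (with structures) or bare
#'   `famsec_structure` objects.
#' @param distance_pairs list of 2-label character vectors (or strings
#'   `"A:B"`).
#' @param dihedral_quads list of 4-label character vectors (or strings
#'   `"A:B:C:D"`).
#' @return data.frame `quantity`, `atoms`, `value_1`, `value_2`, `delta`
#'   (distances in Angstrom, dihedrals in degrees).
#' @export
geometry_change_report <- function(snap_1, snap_2, distance_pairs = list(),
                                   dihedral_quads = list()) {
  s1 <- as_structure(snap_1)
  s2 <- as_structure(snap_2)
  split_item <- function(x, n) {
    lab <- if (length(x) == 1L && grepl(":", x, fixed = TRUE)) {
      strsplit(x, ":", fixed = TRUE)[[1L]]
    } else as.character(x)
    if (length(lab) != n) {
      stop(sprintf("expected %d atom labels, got '%s'", n,
                   paste(x, collapse = ",")), call. = FALSE)
    }
    lab
  }
  rows <- list()
  for (p in distance_pairs) {
    lab <- split_item(p, 2L)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "distance", atoms = paste(lab, collapse = ":"),
      value_1 = atom_distance(s1, lab[1L], lab[2L]),
      value_2 = atom_distance(s2, lab[1L], lab[2L]),
      stringsAsFactors = FALSE)
  }
  for (q in dihedral_quads) {
    lab <- split_item(q, 4L)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "dihedral", atoms = paste(lab, collapse = ":"),
      value_1 = dihedral_angle(s1, lab[1L], lab[2L], lab[3L], lab[4L]),
      value_2 = dihedral_angle(s2, lab[1L], lab[2L], lab[3L], lab[4L]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(quantity = character(0), atoms = character(0),
                      value_1 = numeric(0), value_2 = numeric(0),
                      delta = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$delta <- out$value_2 - out$value_1
  rownames(out) <- NULL
  out
}

as_structure <- function(x) {
  if (inherits(x, "famsec_structure")) return(x)
  if (inherits(x, "famsec_snapshot")) {
    if (is.null(x$structure)) {
      stop(sprintf("snapshot %s has no structure", x$label), call. = FALSE)
    }
    return(x$structure)
  }
  stop("expected a famsec_structure or famsec_snapshot", call. = FALSE)
}
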