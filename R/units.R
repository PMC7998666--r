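#' Energy unit conversion
#'
#' Converts energies between hartree, kcal/mol and kJ/mol using pinned
#' constants: 1 hartree = 627.5094740631 kcal/mol (CODATA-derived) and
#' 1 kcal = 4.184 kJ (thermochemical calorie). The constants are fixed so
#' converted tables are bit-stable across runs.
#'
#' @param value numeric vector of energies.
#' @param from,to unit names, one of `"hartree"`, `"kcal/mol"`, `"kJ/mol"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_units(1, "hartree", "kcal/mol")
#' convert_units(-0.145, "hartree", "kcal/mol")
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value))
  from <- match_unit(from)
  to <- match_unit(to)
  # factors to kcal/mol
  value * .unit_to_kcal[[from]] / .unit_to_kcal[[to]]
}

HARTREE_TO_KCAL <- 627.5094740631
KCAL_TO_KJ <- 4.184

.unit_to_kcal <- list(
  "hartree"  = HARTREE_TO_KCAL,
  "kcal/mol" = 1,
  "kJ/mol"   = 1 / KCAL_TO_KJ
)

match_unit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L) {
    stop("unit must be a single string", call. = FALSE)
  }
  u <- c("hartree", "kcal/mol", "kJ/mol")
  hit <- match(tolower(unit), tolower(u))
  if (is.na(hit)) {
    stop(sprintf("unknown unit '%s' (expected one of %s)",
                 unit, paste(u, collapse = ", ")), call. = FALSE)
  }
  u[hit]
}

#' Coulomb constant used by the synthetic generator,
#' in kcal * Angstrom / (mol * e^2).
#' @keywords internal
COULOMB_K <- 332.0637
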