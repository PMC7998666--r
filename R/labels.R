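# Atom labels are element symbol + 1-based serial ("Li27", "C28"); comparison
# is case-sensitive on this canonical form. Canonical pair ordering is
# lexicographic by (element, serial).

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

is_element <- function(x) x %in% .ELEMENTS

#' Split atom labels into element and serial
#'
#' @param label character vector of labels such as `"Li27"`.
#' @return data.frame with columns `label`, `element`, `serial`.
#' @examples
#' split_atom_label(c("N1", "Li27"))
#' @export
split_atom_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z][a-z]?)([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop(sprintf("malformed atom label(s): %s",
                 paste(label[bad], collapse = ", ")), call. = FALSE)
  }
  el <- vapply(m, `[[`, "", 2L)
  sn <- as.integer(vapply(m, `[[`, "", 3L))
  bad_el <- !is_element(el)
  if (any(bad_el)) {
    stop(sprintf("unknown element symbol in label(s): %s",
                 paste(label[bad_el], collapse = ", ")), call. = FALSE)
  }
  data.frame(label = label, element = el, serial = sn,
             stringsAsFactors = FALSE)
}

# Order labels canonically: by element symbol, then serial.
label_rank <- function(label) {
  p <- split_atom_label(label)
  order(order(p$element, p$serial))
}

# For two parallel label vectors, return them canonically ordered per pair.
canonical_pair <- function(a, b) {
  pa <- split_atom_label(a)
  pb <- split_atom_label(b)
  swap <- (pb$element < pa$element) |
    (pb$element == pa$element & pb$serial < pa$serial)
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

# Sort a label vector canonically.
sort_labels <- function(label) {
  p <- split_atom_label(label)
  label[order(p$element, p$serial)]
}
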