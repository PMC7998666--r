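#' Build a thermochemistry table
#'
#' One row per structure: electronic energy `E`, zero-point corrected energy
#' `E_ZPVE`, enthalpy `H` and Gibbs free energy `G`, all in kcal/mol, at
#' temperature `T` (kelvin). Absent terms are `NA`.
#'
#' @param label structure labels.
#' @param E,E_ZPVE,H,G energies (kcal/mol); may be `NA`.
#' @param T temperature in kelvin, recycled; must be positive.
#' @return object of class `famsec_thermo` (a data.frame).
#' @export
new_thermo <- function(label, E = NA_real_, E_ZPVE = NA_real_,
                       H = NA_real_, G = NA_real_, T = 298.15) {
  n <- length(label)
  out <- data.frame(label = as.character(label),
                    E = rep_len(as.numeric(E), n),
                    E_ZPVE = rep_len(as.numeric(E_ZPVE), n),
                    H = rep_len(as.numeric(H), n),
                    G = rep_len(as.numeric(G), n),
                    T = rep_len(as.numeric(T), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$label)) {
    stop(sprintf("duplicate thermo label(s): %s",
                 paste(unique(out$label[duplicated(out$label)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.na(out$T) & out$T <= 0)) {
    stop("temperature must be positive", call. = FALSE)
  }
  class(out) <- c("famsec_thermo", "data.frame")
  out
}

#' Read an energy summary (CSV)
#'
#' Native format: header `label,E,E_ZPVE,H,G,T,units`; `units` per row is
#' `"kcal/mol"` or `"hartree"` and applies to the four energy columns, which
#' are converted to kcal/mol on read. `T` is kelvin and passes through.
#'
#' @param file path or connection.
#' @return a `famsec_thermo` table in kcal/mol.
#' @export
read_energy_summary <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("label", "E", "E_ZPVE", "H", "G", "T", "units")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop(sprintf("energy summary missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(d) == 0L) return(new_thermo(character(0)))
  for (col in c("E", "E_ZPVE", "H", "G")) {
    d[[col]] <- vapply(seq_len(nrow(d)), function(i) {
      if (is.na(d[[col]][i])) NA_real_
      else convert_units(d[[col]][i], d$units[i], "kcal/mol")
    }, numeric(1))
  }
  new_thermo(d$label, d$E, d$E_ZPVE, d$H, d$G, d$T)
}

#' Write an energy summary (CSV, kcal/mol)
#' @param thermo a `famsec_thermo` table.
#' @param file path or connection.
#' @export
write_energy_summary <- function(thermo, file) {
  stopifnot(inherits(thermo, "famsec_thermo"))
  d <- as.data.frame(thermo)
  d$units <- "kcal/mol"
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
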