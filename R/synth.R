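#' Specification for the synthetic snapshot generator
#'
#' The generator emulates the *shape* of QTAIM/IQA data — paired +/- charge
#' centres, a complete symmetric pair table with a long-range classical part
#' and a short-range covalent part — with a schematic point-charge model:
#' `Vcl(A,B) = k_C Q(A) Q(B) / d(A,B)` with
#' `k_C = 332.0637 kcal Angstrom / (mol e^2)`, and
#' `VXC(A,B) = -s exp(-d / lambda)`. It is a test scaffold, not a physical
#' IQA emulation; changing the algorithm is a breaking change.
#'
#' Defaults: 12 atoms from an organolithium-like palette in an 8 Angstrom
#' box, net charge 0 with 0.5 e dispersion (QTAIM charges in these systems
#' span roughly -1.1 to +0.95 e), XC scale 50 kcal/mol with a 1.5 Angstrom
#' decay length (covalent interactions die off over one to two bond lengths).
#'
#' @param n_atoms number of atoms (>= 2).
#' @param elements element palette to sample from.
#' @param total_charge net charge of the snapshot, e (hit exactly).
#' @param charge_sd dispersion of the raw atomic charges, e.
#' @param box cubic box edge, Angstrom.
#' @param xc_scale prefactor `s` of the XC term, kcal/mol.
#' @param xc_decay decay length `lambda`, Angstrom (> 0).
#' @param min_dist minimum interatomic distance enforced while placing
#'   atoms, Angstrom (keeps 1/d finite).
#' @param seed integer RNG seed; the snapshot is a pure function of the spec.
#' @return object of class `famsec_genspec`.
#' @export
generator_spec <- function(n_atoms = 12L,
                           elements = c("C", "H", "N", "O", "Li"),
                           total_charge = 0, charge_sd = 0.5,
                           box = 8, xc_scale = 50, xc_decay = 1.5,
                           min_dist = 0.8, seed = 1L) {
  if (n_atoms < 2L) stop("n_atoms must be >= 2", call. = FALSE)
  if (box <= 0) stop("box edge must be positive", call. = FALSE)
  if (xc_decay <= 0) stop("xc decay length must be positive", call. = FALSE)
  bad <- !is_element(elements)
  if (any(bad)) {
    stop(sprintf("invalid element(s) in palette: %s",
                 paste(elements[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(n_atoms = as.integer(n_atoms), elements = elements,
                 total_charge = total_charge, charge_sd = charge_sd,
                 box = box, xc_scale = xc_scale, xc_decay = xc_decay,
                 min_dist = min_dist, seed = as.integer(seed)),
            class = "famsec_genspec")
}

#' Generate a synthetic snapshot
#'
#' Draws coordinates uniformly in the box (rejecting placements closer than
#' `min_dist` to an earlier atom), draws charges and shifts them so they sum
#' to `total_charge` exactly, then fills a complete, symmetric pair table
#' from the point-charge/exponential model of [generator_spec()]. The result
#' is deterministic under the spec's seed.
#'
#' @param spec a `famsec_genspec`.
#' @return a `famsec_snapshot` with structure, atom table and pair table.
#' @export
generate_snapshot <- function(spec) {
  stopifnot(inherits(spec, "famsec_genspec"))
  n <- spec$n_atoms
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  el <- sample(spec$elements, n, replace = TRUE)
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      p <- stats::runif(3L, 0, spec$box)
      if (i == 1L) break
      d2 <- colSums((t(xyz[seq_len(i - 1L), , drop = FALSE]) - p)^2)
      if (min(d2) >= spec$min_dist^2) break
      if (try == 1000L) {
        stop("could not place atoms at min_dist; box too small", call. = FALSE)
      }
    }
    xyz[i, ] <- p
  }
  q <- stats::rnorm(n, 0, spec$charge_sd)
  q <- q - mean(q) + spec$total_charge / n

  struct <- new_structure(el, xyz[, 1L], xyz[, 2L], xyz[, 3L],
                          label = sprintf("synthetic seed %d", spec$seed))
  lab <- atom_labels(struct)
  atoms <- new_atom_table(lab, q)

  idx <- utils::combn(n, 2L)
  a <- lab[idx[1L, ]]; b <- lab[idx[2L, ]]
  d <- sqrt(colSums((t(xyz[idx[1L, ], , drop = FALSE]) -
                     t(xyz[idx[2L, ], , drop = FALSE]))^2))
  vcl <- COULOMB_K * q[idx[1L, ]] * q[idx[2L, ]] / d
  vxc <- -spec$xc_scale * exp(-d / spec$xc_decay)
  pairs <- new_pair_table(a, b, vcl, vxc)

  snapshot(sprintf("synthetic-%d", spec$seed), structure = struct,
           atom_table = atoms, pair_table = pairs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a pathway with planted relative energies
#'
#' Builds thermo records whose absolute energies are the planted relative
#' values plus randomly drawn (seed-determined) reference constants for the
#' composition species, so that [build_profile()] recovers the planted
#' values exactly. A planted transition state lying below its predecessor is
#' allowed but warned about, so the downstream barrier flag can be
#' exercised.
#'
#' @param planted data.frame with columns `label`, `role`, `pathway`,
#'   `composition` (a `"+"`-joined species string or list-column) and one
#'   column per planted term among `E`, `E_ZPVE`, `H`, `G` (relative values,
#'   kcal/mol).
#' @param seed integer RNG seed for the species reference energies.
#' @param T temperature stamped on every record, kelvin (default 195.15, the
#'   low-temperature organolithium regime).
#' @return list with `steps` (a `famsec_steps`) and `thermo`
#'   (a `famsec_thermo` covering species and steps).
#' @export
generate_pathway <- function(planted, seed = 1L, T = 195.15) {
  terms <- intersect(.REP_TERMS, names(planted))
  if (!length(terms)) {
    stop("planted table has no energy term column (E, E_ZPVE, H, G)",
         call. = FALSE)
  }
  steps <- reaction_steps(planted$label, planted$role, planted$pathway,
                          planted$composition)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  species <- unique(unlist(steps$composition))
  # hartree-scale molecular totals, in kcal/mol; drawn as whole kcal/mol so
  # that (reference + planted) - reference is bit-exact for planted values
  # on any binary fixed-point grid
  ref <- matrix(round(stats::rnorm(length(species) * length(terms), -3e5, 5e4)),
                nrow = length(species),
                dimnames = list(species, terms))

  for (pw in unique(steps$pathway)) {
    sel <- which(steps$pathway == pw)
    r <- steps$role[sel]
    for (ts_at in which(r == "ts")) {
      if (planted[[terms[1L]]][sel[ts_at]] <
          planted[[terms[1L]]][sel[ts_at - 1L]]) {
        warning(sprintf("pathway %s: planted ts '%s' lies below its predecessor",
                        pw, steps$label[sel[ts_at]]), call. = FALSE)
      }
    }
  }

  th_lab <- c(species, steps$label)
  vals <- lapply(terms, function(tm) {
    ref_sum <- vapply(steps$composition, function(sp) sum(ref[sp, tm]),
                      numeric(1))
    c(ref[, tm], ref_sum + planted[[tm]])
  })
  names(vals) <- terms
  args <- list(label = th_lab, T = T)
  for (tm in terms) args[[tm]] <- vals[[tm]]
  thermo <- do.call(new_thermo, args)
  list(steps = steps, thermo = thermo)
}

#' Worked-example fixtures for the quinoxaline + lithium phenylacetylide
#' system
#'
#' Small snapshots and tables embedding the study system's reference
#' numbers, used throughout the test-suite and the documentation:
#'
#' * `charges`: QTAIM charges Q(Li27) = +0.9463 e, Q(N1) = -1.1164 e,
#'   Q(N4) = -1.1211 e.
#' * `li_c2_pair`: the acetylide Li-C pair record (Vcl, VXC) =
#'   (-90.9, -16.0) kcal/mol, total -106.9, 85/15 percent character.
#' * `nucleophile2`: lithium phenylacetylide head group with
#'   d(Li27, C28) = 2.04 Angstrom and the pair record above.
#' * `adduct3b`: the C3-site adduct with d(Li27, C28) = 2.06 and
#'   d(Li27, N4) = 2.15 Angstrom, the Li-N4 pair totalling -185 kcal/mol at
#'   5 percent XC character, and the C3-C28 pair totalling -20.8 kcal/mol.
#' * `ts4b`: the C3-site transition state where the C3-C28 pair total has
#'   grown to -107.1 kcal/mol.
#' * `intermediates`: steps + thermo placing intermediate 5a at +1.1 and 5b
#'   at -4.9 kcal/mol relative to the separated reactants (gap 6.0).
#'
#' Where only a pair *total* (or total + percent character) is on record,
#' the Vcl/VXC split is synthetic: -185 is split as (-175.75, -9.25) from
#' its 5 percent XC character, the weakened adduct Li-C28 pair is modelled
#' at (-85.0, -15.0) keeping the 15 percent XC character, and the C3-C28
#' totals are split evenly at the adduct (-10.4, -10.4) and
#' covalent-dominated at the TS (-40.0, -67.1) as a forming C-C bond.
#'
#' @return named list of fixtures (see above).
#' @export
worked_example_fixtures <- function() {
  charges <- new_atom_table(c("N1", "N4", "Li27"),
                            c(-1.1164, -1.1211, 0.9463))
  li_c2_pair <- list(a = "C28", b = "Li27", Vcl = -90.9, VXC = -16.0)

  nucleophile2 <- snapshot(
    "2",
    structure = new_structure(c("Li", "C", "C"),
                              x = c(0, 2.04, 3.25), y = c(0, 0, 0),
                              z = c(0, 0, 0), label = "2",
                              serial = c(27L, 28L, 29L)),
    pair_table = new_pair_table("Li27", "C28", -90.9, -16.0)
  )

  adduct3b <- snapshot(
    "3b",
    structure = new_structure(c("N", "C", "Li", "C"),
                              x = c(0, 2.9, 0, 2.06),
                              y = c(2.15, 2.3, 0, 0),
                              z = c(0, 0, 0, 0), label = "3b",
                              serial = c(4L, 3L, 27L, 28L)),
    pair_table = new_pair_table(
      a = c("Li27", "Li27", "C3"),
      b = c("N4", "C28", "C28"),
      Vcl = c(-175.75, -85.0, -10.4),
      VXC = c(-9.25, -15.0, -10.4))
  )

  ts4b <- snapshot(
    "4b",
    pair_table = new_pair_table(
      a = c("Li27", "Li27", "C3"),
      b = c("N4", "C28", "C28"),
      Vcl = c(-170.0, -60.0, -40.0),
      VXC = c(-9.0, -12.0, -67.1))
  )

  planted <- data.frame(
    label = c("reactants-a", "5a", "reactants-b", "5b"),
    role = c("reactant_set", "intermediate", "reactant_set", "intermediate"),
    pathway = c("RP-C2", "RP-C2", "RP-C3", "RP-C3"),
    composition = c("1+2", "1+2", "1+2", "1+2"),
    E = c(0, 1.1, 0, -4.9),
    stringsAsFactors = FALSE)
  steps <- reaction_steps(planted$label, planted$role, planted$pathway,
                          planted$composition)
  thermo <- new_thermo(c("1", "2", "5a", "5b"),
                       E = c(-400000.0, -150000.0,
                             -550000.0 + 1.1, -550000.0 - 4.9),
                       T = 195.15)

  list(charges = charges, li_c2_pair = li_c2_pair,
       nucleophile2 = nucleophile2, adduct3b = adduct3b, ts4b = ts4b,
       intermediates = list(steps = steps, thermo = thermo))
}
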