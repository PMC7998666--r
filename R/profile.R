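.STEP_ROLES <- c("reactant_set", "adduct", "ts", "intermediate", "product")

#' Declare the ordered steps of a reaction pathway
#'
#' Each step names a snapshot, its mechanistic role and the species it is
#' composed of. The composition drives referencing: a step's relative
#' energies are taken against the summed energies of its composition species
#' in isolation, so the reference shifts automatically where a reagent joins
#' mid-profile (e.g. water entering before the hydrolysis adduct).
#'
#' @param label snapshot / thermo labels, in mechanistic order.
#' @param role one of `"reactant_set"`, `"adduct"`, `"ts"`,
#'   `"intermediate"`, `"product"` per step. A `ts` step must be flanked by
#'   non-`ts` steps.
#' @param pathway pathway id per step (e.g. `"RP-C3"`), recycled.
#' @param composition species per step: a list of character vectors, or a
#'   character vector of `"+"`-joined species (e.g. `"1+2"`, `"1+2+H2O"`).
#' @return object of class `famsec_steps` (a data.frame with a
#'   `composition` list-column).
#' @export
reaction_steps <- function(label, role, pathway, composition) {
  n <- length(label)
  role <- rep_len(as.character(role), n)
  bad <- !role %in% .STEP_ROLES
  if (any(bad)) {
    stop(sprintf("unknown role(s): %s (expected %s)",
                 paste(unique(role[bad]), collapse = ", "),
                 paste(.STEP_ROLES, collapse = ", ")), call. = FALSE)
  }
  if (!is.list(composition)) {
    composition <- strsplit(as.character(composition), "+", fixed = TRUE)
  }
  composition <- rep_len(composition, n)
  composition <- lapply(composition, function(x) trimws(as.character(x)))
  if (any(vapply(composition, length, 1L) == 0L)) {
    stop("every step needs a non-empty composition", call. = FALSE)
  }
  out <- data.frame(label = as.character(label), role = role,
                    pathway = rep_len(as.character(pathway), n),
                    stringsAsFactors = FALSE)
  out$composition <- composition
  for (pw in unique(out$pathway)) {
    r <- out$role[out$pathway == pw]
    ts_at <- which(r == "ts")
    flank_bad <- ts_at[ts_at == 1L | ts_at == length(r) |
                       r[pmax(ts_at - 1L, 1L)] == "ts" |
                       r[pmin(ts_at + 1L, length(r))] == "ts"]
    if (length(flank_bad)) {
      stop(sprintf("pathway %s: ts step(s) at position %s not flanked by non-ts steps",
                   pw, paste(flank_bad, collapse = ", ")), call. = FALSE)
    }
  }
  class(out) <- c("famsec_steps", "data.frame")
  out
}

.REP_TERMS <- c("E", "E_ZPVE", "H", "G")

#' Build a reaction energy profile (REP) table
#'
#' For each step and energy term, the relative value is
#' `value(step, term) - sum over the step's composition species of
#' value(species, term)`. A `reactant_set` step with no thermo record of its
#' own is taken as exactly its composition sum, so the reference state sits
#' at zero by construction. All thermo records drawn on must share one
#' temperature; mixed temperatures are an error.
#'
#' @param steps a `famsec_steps` table (or arguments acceptable to it).
#' @param thermo a `famsec_thermo` table holding a record for every step
#'   label (reactant sets excepted) and every composition species.
#' @param terms energy terms to tabulate; default all of `E`, `E_ZPVE`, `H`,
#'   `G` that are fully present. Requesting a term with missing values is an
#'   error.
#' @param t_tol tolerance (kelvin) for temperature equality.
#' @return object of class `famsec_rep`: a data.frame with columns `step`,
#'   `role`, `pathway`, `composition` and one relative-energy column per
#'   term (kcal/mol), plus attributes `terms` and `temperature`.
#' @export
build_profile <- function(steps, thermo, terms = NULL, t_tol = 1e-6) {
  stopifnot(inherits(steps, "famsec_steps"), inherits(thermo, "famsec_thermo"))
  species <- unique(unlist(steps$composition))
  sp_miss <- setdiff(species, thermo$label)
  if (length(sp_miss)) {
    stop(sprintf("no thermo record for composition species: %s",
                 paste(sp_miss, collapse = ", ")), call. = FALSE)
  }
  has_rec <- steps$label %in% thermo$label
  need_rec <- steps$role != "reactant_set"
  if (any(need_rec & !has_rec)) {
    stop(sprintf("no thermo record for step(s): %s",
                 paste(steps$label[need_rec & !has_rec], collapse = ", ")),
         call. = FALSE)
  }
  used <- unique(c(species, steps$label[has_rec]))
  temps <- thermo$T[match(used, thermo$label)]
  if (diff(range(temps)) > t_tol) {
    stop(sprintf("mixed temperatures across profile records (%s): %s",
                 paste(format(sort(unique(temps))), collapse = ", "),
                 paste(used[temps != temps[1L]], collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(terms)) {
    present <- vapply(.REP_TERMS, function(tm) {
      !anyNA(thermo[[tm]][match(used, thermo$label)])
    }, TRUE)
    terms <- .REP_TERMS[present]
    if (!length(terms)) {
      stop("no energy term is complete across all required thermo records",
           call. = FALSE)
    }
  } else {
    terms <- match.arg(terms, .REP_TERMS, several.ok = TRUE)
    for (tm in terms) {
      gap <- used[is.na(thermo[[tm]][match(used, thermo$label)])]
      if (length(gap)) {
        stop(sprintf("term %s missing for record(s): %s", tm,
                     paste(gap, collapse = ", ")), call. = FALSE)
      }
    }
  }
  out <- data.frame(step = steps$label, role = steps$role,
                    pathway = steps$pathway,
                    composition = vapply(steps$composition, paste,
                                         "", collapse = "+"),
                    stringsAsFactors = FALSE)
  for (tm in terms) {
    vals <- thermo[[tm]]
    ref <- vapply(steps$composition, function(sp) {
      sum(vals[match(sp, thermo$label)])
    }, numeric(1))
    abs_val <- ifelse(has_rec, vals[match(steps$label, thermo$label)], ref)
    out[[tm]] <- abs_val - ref
  }
  structure(out, terms = terms, temperature = temps[1L],
            class = c("famsec_rep", "data.frame"))
}

#' @export
print.famsec_rep <- function(x, digits = 1, ...) {
  cat(sprintf("<famsec_rep> %d steps, terms: %s, T = %g K (kcal/mol, relative)\n",
              nrow(x), paste(attr(x, "terms"), collapse = ", "),
              attr(x, "temperature")))
  d <- as.data.frame(x)
  for (tm in attr(x, "terms")) d[[tm]] <- round(d[[tm]], digits)
  print(d)
  invisible(x)
}

#' Energy barrier between two profile entries
#'
#' `relative(ts) - relative(from)` for the chosen term. A negative barrier is
#' allowed but flagged (a transition state below its predecessor indicates
#' inconsistent inputs); a barrier below `negligible` (default 1.5 kcal/mol)
#' is flagged as negligible, the regime of the near-spontaneous hydrolysis
#' transition states.
#'
#' @param rep a `famsec_rep` table.
#' @param ts_label,from_label step labels present in `rep`.
#' @param term one of the table's terms.
#' @param negligible threshold (kcal/mol) below which the barrier is flagged
#'   negligible.
#' @return numeric barrier (kcal/mol) with attributes `flagged` (TRUE when
#'   not positive) and `negligible`.
#' @export
barrier <- function(rep, ts_label, from_label, term = "E",
                    negligible = 1.5) {
  stopifnot(inherits(rep, "famsec_rep"))
  term <- match.arg(term, attr(rep, "terms"))
  for (lb in c(ts_label, from_label)) {
    if (!lb %in% rep$step) {
      stop(sprintf("step '%s' not in REP table", lb), call. = FALSE)
    }
  }
  v <- rep[[term]][match(ts_label, rep$step)] -
       rep[[term]][match(from_label, rep$step)]
  structure(v, flagged = v <= 0, negligible = v < negligible)
}

#' Step-to-step change of a fragment quantity
#'
#' Evaluates one quantity on two snapshots and returns
#' `value(snap_2) - value(snap_1)`. This is the FAMSEC Delta bookkeeping:
#' e.g. the change in a ring's summed covalent (XC) interaction energy from
#' adduct to transition state.
#'
#' @param snap_1,snap_2 `famsec_snapshot` objects with consistent atom
#'   labelling.
#' @param quantity_spec list with `op` and its arguments:
#'   * `op = "intrafragment_sum"`: `frag`, `term`
#'   * `op = "interfragment_energy"`: `frag_a`, `frag_b`, `term`
#'   * `op = "pair_total"`: `a`, `b` (absent pair counts as 0)
#'   * `op = "fragment_charge"`: `frag`
#'   * `op = "distance"`: `a`, `b`
#'   * `op = "dihedral"`: `a`, `b`, `c`, `d`
#' @return list with `delta`, `value_1`, `value_2`, `op` (energies kcal/mol;
#'   charge e; distance Angstrom; dihedral degrees).
#' @export
step_delta <- function(snap_1, snap_2, quantity_spec) {
  stopifnot(inherits(snap_1, "famsec_snapshot"),
            inherits(snap_2, "famsec_snapshot"),
            is.list(quantity_spec), !is.null(quantity_spec$op))
  v1 <- eval_quantity(snap_1, quantity_spec)
  v2 <- eval_quantity(snap_2, quantity_spec)
  list(delta = v2 - v1, value_1 = v1, value_2 = v2, op = quantity_spec$op)
}

eval_quantity <- function(snap, spec) {
  need <- function(part, what) {
    if (is.null(snap[[part]])) {
      stop(sprintf("snapshot %s has no %s (needed for %s)",
                   snap$label, what, spec$op), call. = FALSE)
    }
    snap[[part]]
  }
  switch(spec$op,
    intrafragment_sum = intrafragment_sum(
      need("pair_table", "pair table"), spec$frag,
      term = if (is.null(spec$term)) "total" else spec$term),
    interfragment_energy = interfragment_energy(
      need("pair_table", "pair table"), spec$frag_a, spec$frag_b,
      term = if (is.null(spec$term)) "total" else spec$term)$value,
    pair_total = {
      rec <- pair_lookup(need("pair_table", "pair table"), spec$a, spec$b)
      if (is.null(rec)) 0 else pair_total(rec)
    },
    fragment_charge = fragment_charge(need("atom_table", "atom table"),
                                      spec$frag),
    distance = atom_distance(need("structure", "structure"), spec$a, spec$b),
    dihedral = dihedral_angle(need("structure", "structure"),
                              spec$a, spec$b, spec$c, spec$d),
    stop(sprintf("unknown quantity op '%s'", spec$op), call. = FALSE)
  )
}

#' Compare pathways by barrier and product stability
#'
#' Requires pathways with identical role sequences. For each pathway the
#' barrier is `relative(first ts) - relative(its predecessor)` and the
#' product stability is the last step's relative value. Pathways whose
#' barriers differ by less than `tie_tol` (default 0.1 kcal/mol) are marked
#' comparable.
#'
#' @param reps a single `famsec_rep` covering several pathways, or a list of
#'   `famsec_rep` tables (one per pathway).
#' @param term energy term to compare on.
#' @param tie_tol tie threshold, kcal/mol.
#' @return data.frame `pathway`, `barrier`, `product_stability`, `rank`,
#'   `comparable_group`, sorted by barrier ascending; pathways sharing a
#'   `comparable_group` value are within `tie_tol` of a chain of neighbours.
#' @export
pathway_compare <- function(reps, term = "E", tie_tol = 0.1) {
  if (inherits(reps, "famsec_rep")) reps <- list(reps)
  stopifnot(length(reps) >= 1L)
  one <- do.call(rbind, lapply(reps, function(r) {
    stopifnot(inherits(r, "famsec_rep"))
    term0 <- match.arg(term, attr(r, "terms"))
    as.data.frame(r)[, c("step", "role", "pathway", term0)]
  }))
  pws <- unique(one$pathway)
  if (length(pws) < 2L) {
    stop("pathway_compare needs at least 2 pathways", call. = FALSE)
  }
  role_sig <- vapply(pws, function(pw) {
    paste(one$role[one$pathway == pw], collapse = ">")
  }, "")
  if (length(unique(role_sig)) != 1L) {
    stop(sprintf("pathways have mismatched role structures: %s",
                 paste(sprintf("%s [%s]", pws, role_sig), collapse = "; ")),
         call. = FALSE)
  }
  rows <- lapply(pws, function(pw) {
    d <- one[one$pathway == pw, , drop = FALSE]
    ts_at <- which(d$role == "ts")
    if (!length(ts_at)) {
      stop(sprintf("pathway %s has no ts step", pw), call. = FALSE)
    }
    data.frame(pathway = pw,
               barrier = d[[term]][ts_at[1L]] - d[[term]][ts_at[1L] - 1L],
               product_stability = d[[term]][nrow(d)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$barrier), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  # inclusive tie band (with float slack), so barriers a printed table shows
  # exactly tie_tol apart still read as comparable
  grp <- cumsum(c(TRUE, diff(out$barrier) > tie_tol + 1e-9))
  out$comparable_group <- grp
  rownames(out) <- NULL
  attr(out, "term") <- term
  attr(out, "tie_tol") <- tie_tol
  class(out) <- c("famsec_pathcmp", "data.frame")
  out
}

#' @export
print.famsec_pathcmp <- function(x, ...) {
  cat(sprintf("<pathway comparison> term %s, tie threshold %g kcal/mol\n",
              attr(x, "term"), attr(x, "tie_tol")))
  print(as.data.frame(x))
  sep <- character(0)
  if (nrow(x) > 1L) {
    gaps <- diff(x$barrier)
    sym <- ifelse(gaps <= attr(x, "tie_tol") + 1e-9, " ~ ",
                  ifelse(gaps > 10, " << ", " < "))
    cat("ordering: ", paste0(x$pathway[1L],
        paste0(sym, x$pathway[-1L], collapse = "")), "\n", sep = "")
  }
  invisible(x)
}

#' Read pathway steps and thermo references from YAML
#'
#' Layout:
#' ```
#' thermo: thermo.csv        # optional, relative to the YAML file
#' steps:
#'   - {label: 3b, role: adduct, pathway: RP-C3, composition: [1, 2]}
#'   - {label: 4b, role: ts,     pathway: RP-C3, composition: [1, 2]}
#' ```
#'
#' @param file path to YAML.
#' @return list with `steps` (a `famsec_steps`) and `thermo` (a
#'   `famsec_thermo` or `NULL` when the file names none).
#' @export
read_pathway_yaml <- function(file) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$steps) || !length(doc$steps)) {
    stop("pathway.yaml must contain a non-empty 'steps' list", call. = FALSE)
  }
  get_field <- function(nm) lapply(doc$steps, function(s) {
    if (is.null(s[[nm]])) {
      stop(sprintf("pathway step missing field '%s'", nm), call. = FALSE)
    }
    s[[nm]]
  })
  steps <- reaction_steps(
    label = unlist(get_field("label")),
    role = unlist(get_field("role")),
    pathway = unlist(get_field("pathway")),
    composition = lapply(get_field("composition"), function(x)
      as.character(unlist(x)))
  )
  thermo <- NULL
  if (!is.null(doc$thermo)) {
    path <- doc$thermo
    if (!file.exists(path)) path <- file.path(dirname(file), doc$thermo)
    thermo <- read_energy_summary(path)
  }
  list(steps = steps, thermo = thermo)
}
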