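test_that("the reference state sits at zero and offsets subtract through", {
  fx <- worked_example_fixtures()
  rep <- build_profile(fx$intermediates$steps, fx$intermediates$thermo)
  expect_equal(rep$E[rep$role == "reactant_set"], c(0, 0))
  expect_equal(rep$E[rep$step == "5a"], 1.1, tolerance = 1e-6)
  expect_equal(rep$E[rep$step == "5b"], -4.9, tolerance = 1e-6)
  expect_equal(rep$E[rep$step == "5a"] - rep$E[rep$step == "5b"], 6.0,
               tolerance = 1e-6)
})

test_that("relative values equal hand subtraction for random absolutes", {
  set.seed(61)
  for (i in 1:20) {
    abs_e <- stats::rnorm(5, -1000, 50)
    th <- new_thermo(c("1", "2", "s1", "s2", "s3"),
                     E = abs_e, T = 195.15)
    steps <- reaction_steps(c("s1", "s2", "s3"),
                            c("adduct", "ts", "intermediate"),
                            "RP-X", "1+2")
    rep <- build_profile(steps, th)
    ref <- abs_e[1] + abs_e[2]
    expect_equal(rep$E, abs_e[3:5] - ref, tolerance = 1e-9)
  }
})

test_that("a composition change mid-profile re-references that segment", {
  th <- new_thermo(c("1", "2", "H2O", "5b", "6b"),
                   G = c(-100, -200, -50, -315, -365), T = 195.15)
  steps <- reaction_steps(c("5b", "6b"),
                          c("intermediate", "adduct"),
                          "RP-C3",
                          list(c("1", "2"), c("1", "2", "H2O")))
  rep <- build_profile(steps, th)
  expect_equal(rep$G[rep$step == "5b"], -15)  # vs 1+2
  expect_equal(rep$G[rep$step == "6b"], -15)  # vs 1+2+H2O
})

test_that("missing thermo terms and mixed temperatures are errors", {
  th <- new_thermo(c("1", "2", "s1"), E = c(-1, -2, -4),
                   G = c(NA, -2, -4), T = 195.15)
  steps <- reaction_steps("s1", "adduct", "RP-X", "1+2")
  expect_error(build_profile(steps, th, terms = "G"), "missing for record")
  expect_silent(build_profile(steps, th, terms = "E"))
  # default term selection drops the incomplete G
  expect_identical(attr(build_profile(steps, th), "terms"), "E")

  th2 <- new_thermo(c("1", "2", "s1"), E = c(-1, -2, -4),
                    T = c(195.15, 298.15, 195.15))
  expect_error(build_profile(steps, th2), "mixed temperatures")
  th3 <- new_thermo(c("1", "2"), E = c(-1, -2), T = 195.15)
  expect_error(build_profile(steps, th3), "no thermo record for step")
})

test_that("ts steps must be flanked by non-ts steps", {
  expect_error(reaction_steps(c("a", "b"), c("ts", "intermediate"),
                              "RP-X", "1+2"), "flanked")
  expect_error(reaction_steps(c("a", "b", "c"),
                              c("adduct", "ts", "ts"), "RP-X", "1+2"),
               "flanked")
  expect_silent(reaction_steps(c("a", "b", "c"),
                               c("adduct", "ts", "intermediate"),
                               "RP-X", "1+2"))
})

test_that("profiles are gauge invariant under segment-wide shifts", {
  set.seed(62)
  for (i in 1:100) {
    planted <- random_planted_pathway()
    pw <- suppressWarnings(generate_pathway(planted, seed = i))
    rep1 <- build_profile(pw$steps, pw$thermo)
    shift <- round(stats::runif(1, -500, 500))
    th2 <- pw$thermo
    # shift species "1" and every step by the same constant: the reference
    # moves with the steps, so the profile must not change
    th2$E <- th2$E + shift
    th2$E[th2$label == "2"] <- th2$E[th2$label == "2"] - shift
    rep2 <- build_profile(pw$steps, th2)
    expect_equal(rep2$E, rep1$E, tolerance = 1e-9)
  }
})

test_that("barriers subtract profile entries and carry flags", {
  planted <- data.frame(
    label = c("r", "3", "4", "5"),
    role = c("reactant_set", "adduct", "ts", "intermediate"),
    pathway = "RP-C3", composition = "1+2",
    E = c(0, -2.6, 15, -4.9), stringsAsFactors = FALSE)
  pw <- generate_pathway(planted, seed = 3)
  rep <- build_profile(pw$steps, pw$thermo)
  b <- barrier(rep, "4", "3", term = "E")
  expect_equal(as.numeric(b), 17.6, tolerance = 1e-9)
  expect_false(attr(b, "flagged"))
  expect_false(attr(b, "negligible"))

  z <- barrier(rep, "3", "3", term = "E")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))
  expect_true(attr(z, "negligible"))
  expect_error(barrier(rep, "nope", "3"), "not in REP")
})

test_that("a ~1 kcal/mol hydrolysis-type barrier is flagged negligible", {
  th <- new_thermo(c("1", "2", "H2O", "6a", "7a", "8a"),
                   G = c(-100, -200, -50, -370, -369, -400), T = 195.15)
  steps <- reaction_steps(c("6a", "7a", "8a"),
                          c("adduct", "ts", "product"),
                          "RP-C2", list(c("1", "2", "H2O")))
  rep <- build_profile(steps, th)
  b <- barrier(rep, "7a", "6a", term = "G")
  expect_equal(as.numeric(b), 1.0, tolerance = 1e-9)
  expect_true(attr(b, "negligible"))
  expect_false(attr(b, "flagged"))
})

test_that("forward and reverse barriers reconstruct the step difference", {
  set.seed(63)
  for (i in 1:25) {
    planted <- random_planted_pathway(n_mid = 2L)
    pw <- suppressWarnings(generate_pathway(planted, seed = 1000 + i))
    rep <- build_profile(pw$steps, pw$thermo)
    ts_at <- which(rep$role == "ts")[1L]
    fwd <- as.numeric(barrier(rep, rep$step[ts_at], rep$step[ts_at - 1L], "E"))
    rev_ <- as.numeric(barrier(rep, rep$step[ts_at], rep$step[ts_at + 1L], "E"))
    expect_equal(fwd - rev_,
                 rep$E[ts_at + 1L] - rep$E[ts_at - 1L], tolerance = 1e-9)
  }
})

test_that("step_delta recovers printed pair-energy changes and is antisymmetric", {
  fx <- worked_example_fixtures()
  spec <- list(op = "pair_total", a = "C3", b = "C28")
  d <- step_delta(fx$adduct3b, fx$ts4b, spec)
  expect_equal(d$value_1, -20.8)
  expect_equal(d$value_2, -107.1)
  expect_equal(d$delta, -86.3)
  # identical snapshots give zero for any quantity
  expect_equal(step_delta(fx$adduct3b, fx$adduct3b, spec)$delta, 0)
  expect_equal(step_delta(
    fx$adduct3b, fx$adduct3b,
    list(op = "interfragment_energy", frag_a = "Li27",
         frag_b = c("N4", "C28")))$delta, 0)
})

test_that("step_delta is antisymmetric on random snapshots", {
  set.seed(64)
  for (i in 1:100) {
    s1 <- generate_snapshot(generator_spec(n_atoms = 6L, seed = i))
    s2 <- generate_snapshot(generator_spec(n_atoms = 6L, seed = i + 5000L))
    u <- snapshot_universe(s1)
    spec <- list(op = "intrafragment_sum", frag = sample(u, 3L), term = "xc")
    a <- step_delta(s1, s2, spec)$delta
    b <- step_delta(s2, s1, spec)$delta
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("pathway_compare orders barriers with comparability marks", {
  mk <- function(pathway, barrier_val) {
    data.frame(label = paste0(pathway, c("-r", "-3", "-4", "-5")),
               role = c("reactant_set", "adduct", "ts", "intermediate"),
               pathway = pathway, composition = "1+2",
               E = c(0, -2, -2 + barrier_val, -4),
               stringsAsFactors = FALSE)
  }
  planted <- rbind(mk("RP-C2", 18), mk("RP-C3", 16),
                   mk("RP-C5", 36.8), mk("RP-C10", 36.7))
  pw <- generate_pathway(planted, seed = 9)
  rep <- build_profile(pw$steps, pw$thermo)
  cmp <- pathway_compare(rep, term = "E")
  expect_identical(cmp$pathway, c("RP-C3", "RP-C2", "RP-C10", "RP-C5"))
  expect_equal(cmp$barrier, c(16, 18, 36.7, 36.8), tolerance = 1e-9)
  # C5 and C10 are within 0.1 kcal/mol: same comparability group
  expect_identical(cmp$comparable_group[3L], cmp$comparable_group[4L])
  expect_false(cmp$comparable_group[1L] == cmp$comparable_group[2L])
})

test_that("identical pathways tie and mismatched role structures error", {
  mk <- function(pathway, roles = c("reactant_set", "adduct", "ts", "product")) {
    data.frame(label = paste0(pathway, "-", seq_along(roles)),
               role = roles, pathway = pathway, composition = "1+2",
               E = c(0, -2, 14, -6)[seq_along(roles)],
               stringsAsFactors = FALSE)
  }
  pw <- generate_pathway(rbind(mk("A"), mk("B")), seed = 10)
  cmp <- pathway_compare(build_profile(pw$steps, pw$thermo), term = "E")
  expect_identical(cmp$comparable_group[1L], cmp$comparable_group[2L])

  bad <- rbind(mk("A"),
               mk("B", c("reactant_set", "ts", "intermediate", "product")))
  pw2 <- suppressWarnings(generate_pathway(bad, seed = 11))
  expect_error(pathway_compare(build_profile(pw2$steps, pw2$thermo), "E"),
               "mismatched role")
  one <- generate_pathway(mk("A"), seed = 12)
  expect_error(pathway_compare(build_profile(one$steps, one$thermo), "E"),
               "at least 2")
})

test_that("random pathway comparisons match an exhaustive sort", {
  set.seed(65)
  for (i in 1:20) {
    n_pw <- sample(3:5, 1L)
    planted <- do.call(rbind, lapply(seq_len(n_pw), function(j) {
      b <- round(stats::runif(1, 1, 40), 3)
      data.frame(label = paste0("P", j, "-", 1:4),
                 role = c("reactant_set", "adduct", "ts", "product"),
                 pathway = paste0("P", j), composition = "1+2",
                 E = c(0, -1, -1 + b, -3), stringsAsFactors = FALSE)
    }))
    pw <- generate_pathway(planted, seed = 100 + i)
    cmp <- pathway_compare(build_profile(pw$steps, pw$thermo), "E")
    expect_false(is.unsorted(cmp$barrier))
    expect_identical(cmp$rank, seq_len(n_pw))
  }
})

test_that("pathway YAML round-trips steps and thermo references", {
  dir <- withr::local_tempdir()
  th <- new_thermo(c("1", "2", "3b", "4b", "5b"),
                   E = c(-100, -200, -305, -290, -306),
                   G = c(-90, -190, -283, -270, -284), T = 195.15)
  write_energy_summary(th, file.path(dir, "thermo.csv"))
  yml <- file.path(dir, "pathway.yaml")
  writeLines(c(
    "thermo: thermo.csv",
    "steps:",
    "  - {label: 3b, role: adduct, pathway: RP-C3, composition: ['1', '2']}",
    "  - {label: 4b, role: ts, pathway: RP-C3, composition: ['1', '2']}",
    "  - {label: 5b, role: intermediate, pathway: RP-C3, composition: ['1', '2']}"
  ), yml)
  pw <- read_pathway_yaml(yml)
  rep <- build_profile(pw$steps, pw$thermo)
  expect_equal(rep$E, c(-5, 10, -6))
  expect_equal(as.numeric(barrier(rep, "4b", "3b", "E")), 15)
})
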