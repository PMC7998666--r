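test_that("unit conversions use the pinned constants and compose", {
  expect_identical(convert_units(0, "hartree", "kcal/mol"), 0)
  expect_equal(convert_units(1, "hartree", "kcal/mol"), 627.5094740631)
  expect_equal(convert_units(1, "kcal/mol", "kJ/mol"), 4.184)
  set.seed(11)
  x <- stats::rnorm(50, 0, 100)
  # inverse composition
  back <- convert_units(convert_units(x, "hartree", "kcal/mol"),
                        "kcal/mol", "hartree")
  expect_equal(back, x, tolerance = 1e-12)
  # path independence: hartree -> kJ equals hartree -> kcal -> kJ
  expect_equal(convert_units(x, "hartree", "kJ/mol"),
               convert_units(convert_units(x, "hartree", "kcal/mol"),
                             "kcal/mol", "kJ/mol"),
               tolerance = 1e-10)
  expect_error(convert_units(1, "eV", "kcal/mol"), "unknown unit")
})

test_that("read_xyz parses minimal and axis-aligned files", {
  s <- read_xyz(textConnection("1\n\nLi 0.0 0.0 0.0"))
  expect_equal(nrow(s$atoms), 1L)
  expect_identical(atom_labels(s), "Li1")
  expect_equal(unlist(s$atoms[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))

  s2 <- read_xyz(textConnection("2\ndimer\nC 0 0 0\nC 0 0 1.2"))
  expect_identical(s2$label, "dimer")
  expect_equal(atom_distance(s2, "C1", "C2"), 1.2)
})

test_that("read_xyz reports count mismatches and bad coordinates by line", {
  expect_error(read_xyz(textConnection("3\n\nC 0 0 0\nC 0 0 1")),
               "count mismatch")
  expect_error(read_xyz(textConnection("1\n\nC 0 0 0\nC 1 1 1")),
               "count mismatch")
  expect_error(read_xyz(textConnection("1\n\nC 0 zero 0")),
               "line 3.*non-numeric")
})

test_that("XYZ write/read round-trips random structures", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_structure(n = 5L)
    f <- withr::local_tempfile(fileext = ".xyz")
    write_xyz(s, f)
    s2 <- read_xyz(f)
    expect_identical(s2$atoms$element, s$atoms$element)
    expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
                 as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-9)
    expect_identical(s2$label, s$label)
  }
})

test_that("pair tables store unordered pairs once with symmetric lookup", {
  f <- textConnection("A,B,Vcl,VXC\nLi27,C28,-90.9,-16.0")
  pt <- read_pair_table(f)
  expect_equal(nrow(pt), 1L)
  # canonical storage: C before Li lexicographically by element
  expect_identical(pt$a, "C28")
  expect_identical(pt$b, "Li27")
  r1 <- pair_lookup(pt, "Li27", "C28")
  r2 <- pair_lookup(pt, "C28", "Li27")
  expect_identical(r1, r2)
  expect_equal(r1$Vcl, -90.9)
  expect_equal(r1$VXC, -16.0)
})

test_that("pair-table duplicates deduplicate when equal and error when not", {
  both_dirs <- "A,B,Vcl,VXC\nC1,N2,-5.0,-2.0\nN2,C1,-5.0,-2.0"
  pt <- read_pair_table(textConnection(both_dirs))
  expect_equal(nrow(pt), 1L)
  conflict <- "A,B,Vcl,VXC\nC1,N2,-5.0,-2.0\nN2,C1,-5.0,-2.5"
  expect_error(read_pair_table(textConnection(conflict)),
               "conflicting duplicate.*C1.*N2")
  expect_error(new_pair_table("C1", "C1", 1, 1), "self-pair")
})

test_that("pair tables read hartree input converted to kcal/mol", {
  f <- textConnection("A,B,Vcl,VXC\nC1,N2,-0.1,-0.02")
  pt <- read_pair_table(f, units = "hartree")
  expect_equal(pt$Vcl, -0.1 * 627.5094740631)
  expect_equal(pt$VXC, -0.02 * 627.5094740631)
  expect_error(read_pair_table(textConnection("A,B,Vcl,VXC"), units = "eV"),
               "unknown unit")
  empty <- read_pair_table(textConnection("A,B,Vcl,VXC"))
  expect_equal(nrow(empty), 0L)
})

test_that("atom tables carry charges in e and reject duplicates", {
  f <- textConnection("label,element,Q\nN1,N,-1.1164\nLi27,Li,0.9463")
  at <- read_atom_table(f)
  expect_equal(at$Q[at$label == "N1"], -1.1164)
  expect_equal(at$Q[at$label == "Li27"], 0.9463)
  expect_error(new_atom_table(c("N1", "N1"), c(0, 1)), "duplicate")
  empty <- read_atom_table(textConnection("label,element,Q"))
  expect_equal(nrow(empty), 0L)
})

test_that("atom and pair CSV writers round-trip", {
  set.seed(31)
  rp <- random_pair_table(6L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(rp$pairs, f)
  expect_equal(read_pair_table(f), rp$pairs, tolerance = 1e-9)

  at <- new_atom_table(rp$labels, stats::rnorm(6), stats::rnorm(6))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_atom_table(at, f2)
  expect_equal(read_atom_table(f2), at, tolerance = 1e-9)
})

test_that("energy summaries convert units per row and round-trip", {
  csv <- paste("label,E,E_ZPVE,H,G,T,units",
               "3b,-1000.5,-998.0,-997.5,-1010.0,195.15,kcal/mol",
               "4b,-1.6,-1.59,-1.58,-1.61,195.15,hartree", sep = "\n")
  th <- read_energy_summary(textConnection(csv))
  expect_equal(th$T, c(195.15, 195.15))
  expect_equal(th$E[1], -1000.5)
  expect_equal(th$E[2], -1.6 * 627.5094740631)

  f <- withr::local_tempfile(fileext = ".csv")
  write_energy_summary(th, f)
  expect_equal(read_energy_summary(f), th, tolerance = 1e-9)

  empty <- read_energy_summary(
    textConnection("label,E,E_ZPVE,H,G,T,units"))
  expect_equal(nrow(empty), 0L)
})

test_that("simplified AIMAll dialect parses both sections with conversion", {
  txt <- paste("# annotated example",
               "[Atomic Properties]",
               "Atom   q(A)",
               "Li27   0.9463",
               "C28   -0.8000",
               "",
               "[IQA Pairwise]",
               "A      B      Vcl(A,B)    VXC(A,B)",
               "Li27   C28    -0.145      -0.0255", sep = "\n")
  out <- read_aimall_sum(textConnection(txt))
  expect_equal(out$atoms$Q[out$atoms$label == "Li27"], 0.9463)
  # hand conversion oracle
  expect_equal(pair_lookup(out$pairs, "Li27", "C28")$Vcl,
               -0.145 * 627.5094740631)
  expect_equal(pair_lookup(out$pairs, "C28", "Li27")$VXC,
               -0.0255 * 627.5094740631)
})

test_that("AIMAll dialect handles atoms-only files, zeros and errors", {
  atoms_only <- "[Atomic Properties]\nAtom q(A)\nC1 0.1\nH2 -0.1"
  out <- read_aimall_sum(textConnection(atoms_only))
  expect_equal(nrow(out$pairs), 0L)

  zero <- paste("[Atomic Properties]", "Atom q(A)", "C1 0.0", "H2 0.0",
                "[IQA Pairwise]", "A B Vcl(A,B) VXC(A,B)",
                "C1 H2 0.0 0.0", sep = "\n")
  outz <- read_aimall_sum(textConnection(zero))
  expect_identical(pair_lookup(outz$pairs, "C1", "H2")$Vcl, 0)

  expect_error(read_aimall_sum(textConnection("[IQA Pairwise]\nA B Vcl(A,B) VXC(A,B)")),
               "\\[Atomic Properties\\]")
  bad <- paste("[Atomic Properties]", "Atom q(A)", "C1 0.1",
               "[IQA Pairwise]", "A B Vcl(A,B) VXC(A,B)",
               "C1 H2 -0.1", sep = "\n")
  expect_error(read_aimall_sum(textConnection(bad)), "line 6")
})

test_that("the shipped annotated .sum example parses and balances", {
  f <- system.file("extdata", "example.sum", package = "famsec")
  out <- read_aimall_sum(f)
  expect_equal(nrow(out$atoms), 3L)
  expect_equal(nrow(out$pairs), 3L)
  expect_equal(pair_lookup(out$pairs, "C28", "Li27")$Vcl,
               -0.144861 * 627.5094740631)
  # the shipped fragments.yaml resolves over the full universe
  fy <- system.file("extdata", "fragments.yaml", package = "famsec")
  fs <- read_fragments_yaml(fy)
  lib <- quinoxaline_fragment_library()
  for (nm in names(fs)) {
    expect_setequal(fs[[nm]]$members, lib[[nm]]$members)
  }
})
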