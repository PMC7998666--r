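Package: famsec
Title: Fragment-Attributed Decomposition of IQA Interaction Energies and
    Reaction Energy Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for Quantum Theory of Atoms in Molecules
    (QTAIM) / Interacting Quantum Atoms (IQA) output: readers for XYZ
    structures, atomic-property and pairwise interaction-energy tables and
    thermochemistry summaries; named molecular fragments with range notation;
    interfragment and intra-fragment energy sums split into classical
    (coulombic) and exchange-correlation (covalent) components; reaction
    energy profile (REP) assembly across multi-step pathways with barriers,
    step-to-step energy changes and pathway comparison; geometric diagnostics
    (distances, dihedrals, van der Waals contacts); and a seeded synthetic
    snapshot generator for testing without quantum-chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
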