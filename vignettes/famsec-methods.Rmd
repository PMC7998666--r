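---
title: "Fragment-attributed IQA energy decomposition and reaction energy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-attributed IQA energy decomposition and reaction energy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsec)
```

## The problem this package addresses

Quantum-chemical studies of organic reaction mechanisms routinely produce two
kinds of output that are hard to connect by hand. On one side sit reaction
energy profiles (REPs): electronic energies, zero-point corrected energies,
enthalpies and Gibbs free energies of the stationary points along each
candidate pathway. On the other side sits an Interacting Quantum Atoms (IQA)
decomposition of each stationary point, which partitions the total energy
into atomic self-energies and pairwise interatomic interaction energies, each
pair split into a classical (coulombic) component `Vcl(A,B)` and an
exchange-correlation (covalent) component `VXC(A,B)`. QTAIM supplies the
companion per-atom net charges `Q(A)`.

The fragment-attributed bookkeeping implemented here (FAMSEC-style analysis)
connects the two: group atoms into chemically meaningful fragments, sum the
pairwise IQA terms between and within fragments, follow those sums from one
mechanistic step to the next, and line the resulting interaction picture up
against the barriers of the REP. The package's reference use case is the
nucleophilic addition of lithium phenylacetylide to 2-phenylquinoxaline — a
system with four electrophilic carbons (C2, C3, C5, C10) and hence four
competing pathways — followed by hydrolysis of the resulting intermediates,
but every operation is generic over atom labels.

The package deliberately performs **no** quantum chemistry: geometry
optimisation, frequencies, IRC following, basin integration and the IQA terms
themselves are all upstream. It consumes their tabulated results.

## Core quantities

For a pair table `V = {Vcl(A,B), VXC(A,B)}` over unordered atom pairs, and
fragments `F`, `G` (disjoint sets of atom labels):

* pair total: `V(A,B) = Vcl(A,B) + VXC(A,B)`; attraction is negative
  throughout.
* interfragment energy:
  `E_int(F,G) = sum over A in F, B in G of V(A,B)`, with per-component
  variants. Each unordered pair is counted exactly once and never halved,
  which makes two invariants hold *exactly* (up to float rounding):
  additivity, `E_int(F1 u F2, G) = E_int(F1,G) + E_int(F2,G)`, and
  completeness — interfragment sums over a partition plus all intra-fragment
  sums reproduce the grand total of the table.
* intra-fragment sum: the same sum restricted to internal pairs of one
  fragment. With the XC component this is the "summed covalent interaction
  energy" of a ring or moiety; its step-to-step change diagnoses where
  aromatic stabilisation is being built up or destroyed at a transition
  state.
* percent character: `(100 Vcl / V, 100 VXC / V)`, undefined at `V = 0`. The
  components re-sum to 100 before rounding by construction.
* fragment charge: `Q(F) = sum of Q(A)`.

Pairs absent from a table contribute exactly zero and are reported through
`n_pairs_counted`, so sparse (thresholded) tables are legal inputs; callers
who consider absence an integrity problem use `strict = TRUE`.

### The transition-state lithium convention

At the nucleophilic-addition transition state the lithium atom sits between
the breaking Li–C bond and the forming Li–N bond, so no assignment of Li to
either molecule is defensible. Rather than switching conventions silently
per step role, the package makes the partition an explicit caller choice:
pass `{molecule 1}`, `{Li27}`, `{R}` (molecule 2 minus lithium) as three
fragments and every result carries the fragment names it was computed from.

## Reaction energy profiles

`build_profile()` turns ordered, role-annotated steps plus a thermochemistry
table into relative energies. Each step declares its *composition* — the
isolated species it is built from (`1+2` at the addition stage, `1+2+H2O`
once water joins before hydrolysis). The relative value of a step is its
absolute energy minus the summed absolute energies of its composition
species. This keeps one continuous profile across a mid-profile reagent
addition, because the reference moves with the composition; it is also what
makes the table gauge invariant (shifting any species and all steps
containing it by a constant changes nothing).

Design choices worth knowing:

* A `reactant_set` step without its own thermo record is taken to *be* its
  composition sum, hence exactly zero — the definition of the reference.
* All four terms (`E`, `E_ZPVE`, `H`, `G`) are tabulated whenever complete;
  any scalar question (a barrier, a comparison) takes the term as an
  argument. Reports never privilege one term because the terms track each
  other closely in the reference system but not in general.
* Temperature is metadata. Thermal corrections are never recomputed, and
  mixing records computed at different temperatures in one profile is an
  error (the reference analysis is single-temperature, 195.15 K, the low
  temperature organolithium chemistry is run at).
* `barrier()` is a plain difference `rel(ts) - rel(from)`. A non-positive
  barrier is flagged rather than rejected — it is how inconsistent inputs
  surface. Barriers under 1.5 kcal/mol carry a `negligible` flag
  (configurable); ~1 kcal/mol is the regime of the effectively spontaneous
  hydrolysis transition states.
* `pathway_compare()` requires identical role sequences, ranks pathways by
  the barrier at the first transition state, and marks pathways whose
  barriers differ by at most 0.1 kcal/mol (configurable, inclusive with a
  1e-9 float slack so values a table prints exactly 0.1 apart still tie) as
  comparable.

`step_delta()` is the Delta bookkeeping between consecutive snapshots: it
evaluates one named quantity (an interfragment or intra-fragment sum, a pair
total, a fragment charge, a distance or a dihedral) on two snapshots and
returns the difference, `value(later) - value(earlier)`. It is antisymmetric
by construction.

## Geometry diagnostics

Distances are Euclidean; dihedrals use the right-hand (IUPAC) signed torsion
in `(-180, 180]`. Note that the signed torsion is *invariant* under reversing
the atom order (`chi(a,b,c,d) = chi(d,c,b,a)`); the sign flips when the
fourth atom is mirrored through the plane of the first three. Three
consecutive collinear atoms (cross-product norm below 1e-10 squared
Angstrom) make the torsion undefined and raise an error. Van der Waals
contacts use strict inequality against the radii sum, with the Bondi (1964)
radii bundled as the default table — the choice is explicit and swappable
because published contact claims rarely state their radii set.

## File formats and units

Native tables are comma-delimited UTF-8 with required headers
(`atoms.csv`: label, element, Q, optional E_self; `pairs.csv`: A, B, Vcl,
VXC; thermo: label, E, E_ZPVE, H, G, T, units). Pair tables store each
unordered pair once, canonically ordered lexicographically by (element,
serial); duplicate rows with equal values are deduplicated, conflicting ones
are an integrity error. A simplified AIMAll-style `.sum` dialect (two fixed
headers, hartree energies; annotated example under `inst/extdata/`) covers
the common hand-off from basin-integration software; parsing full vendor
outputs is out of scope. Structures are standard XYZ — which carries no
serials, so atoms are renumbered 1..N on read; partial structures built in
code may keep a parent system's numbering.

Unit conversions are pinned to 1 hartree = 627.5094740631 kcal/mol and
1 kcal = 4.184 kJ (thermochemical), so converted tables are bit-stable.
Everything internal is kcal/mol, Angstrom, e, kelvin, degrees.

Fragment specifications use the field's range notation: `"N1-H15"` spans
serials 1..15 *regardless of element*, because printed fragment sets mix
elements inside one range. The bundled
`quinoxaline_fragment_library()` encodes the sixteen fragments of the
reference system literally as printed, including the literal reading of the
pyrazine ring as `{N1, C2, C3, N4, C5, C10, H11}`.

## The synthetic generator

`generate_snapshot()` exists so every computation is testable without
quantum-chemistry runs. It is physically schematic by design: coordinates
uniform in a box (with a minimum-distance rejection so `1/d` stays finite),
charges drawn and shifted to hit the requested net charge exactly, and then

* `Vcl(A,B) = 332.0637 * Q(A) Q(B) / d(A,B)` (kcal, Angstrom, e),
* `VXC(A,B) = -s * exp(-d / lambda)`.

The defaults (12 atoms from a C/H/N/O/Li palette, 8 Angstrom box, net charge
0 with 0.5 e dispersion, `s` = 50 kcal/mol, `lambda` = 1.5 Angstrom) mimic
the *statistics* of the reference data — charges spanning roughly -1.1 to
+1 e, covalent terms dying off over a bond length or two — not its physics.
What the generated tables share with real IQA output, by construction, is
exactly what the toolkit relies on: completeness, symmetry, the sign law
`Vcl > 0 iff Q(A)Q(B) > 0`, and determinism under a seed. What they do not
have is real electronic structure: no bonds, no ring currents, no
self-energies, no correlation between VXC and bonding patterns. Passing
property suites on synthetic data therefore certifies the *bookkeeping*, not
any physical prediction.

`generate_pathway()` plants known relative energies and adds randomly drawn
reference constants per species. The constants are drawn as whole kcal/mol
so that `(reference + planted) - reference` is bit-exact for planted values
on any binary fixed-point grid — the recovery property tests assert a
maximum error of exactly zero over 100 seeds, not a tolerance.

`worked_example_fixtures()` packages the reference system's printed numbers
(the Li–C acetylide pair at (-90.9, -16.0) kcal/mol; the -185 kcal/mol Li–N4
attraction at 5% XC character; intermediates at +1.1 / -4.9 kcal/mol versus
the reactants; the 2.04 / 2.06 / 2.15 Angstrom lithium distances). Where
only a total or a percent split is on record, the component split is
synthetic and documented as such in the fixture help page.

## Problem sizes and numerical choices

The test-suite's randomized suites use 5–12-atom snapshots and 4–7-step
pathways, 100 instances per invariant — sizes at which the brute-force
double-loop oracles are trivially affordable while still exercising every
code path; the suite runs in well under a minute. Tolerances: structural
identities (additivity, completeness, gauge invariance) at 1e-9 kcal/mol;
pure float identities (oracle sums, antisymmetry) at 1e-12; rigid-motion
invariance of dihedrals at 1e-6 degrees, reflecting the conditioning of
`atan2` near collinearity. Ties in interaction ranking are broken by
canonical pair order so output is deterministic.

## Limitations

* No self-energy (intra-atomic deformation) terms and no composite
  localized/molecular-fragment energy-change statistics beyond the
  interaction sums above; the inputs this package reads do not carry them.
* No automatic fragment detection from connectivity; fragments are declared.
* The `.sum` reader covers the documented simplified dialect only.
* XYZ renumbering means cross-snapshot work must keep consistent labelling
  upstream, or construct structures in code with explicit serials.
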