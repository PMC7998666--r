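# famsec

Fragment-attributed decomposition of IQA interaction energies and reaction
energy profiles, in R.

## What problem it solves, and for whom

Computational chemists studying multi-pathway reaction mechanisms end up with
two disconnected piles of numbers: reaction energy profiles (relative *E*,
*E*<sub>ZPVE</sub>, *H*, *G* of stationary points along each pathway) and,
per stationary point, a QTAIM/IQA decomposition — net atomic charges *Q*(A)
and pairwise interaction energies split into a classical and an
exchange-correlation component, *V*(A,B) = *V*<sub>cl</sub>(A,B) +
*V*<sub>XC</sub>(A,B). This package does the bookkeeping that connects them:

* **fragments** — named atom sets with the field's range notation
  (`"N1-H15"` spans serials 1–15 across elements), including the bundled
  16-fragment library for the 2-phenylquinoxaline + lithium phenylacetylide
  system;
* **energetics** — interfragment and intra-fragment sums
  E<sub>int</sub>(F,G) = Σ<sub>A∈F, B∈G</sub> V(A,B) with exact additivity
  and completeness (each unordered pair counted once), percent
  classical/covalent character, fragment charges, ranked strongest
  interactions;
* **profiles** — REP tables referenced against each step's declared species
  composition (so a reagent joining mid-profile re-references its segment
  automatically), barriers with negligibility flags, step-to-step Δ of any
  fragment quantity, and multi-pathway comparison with comparability ties;
* **geometry** — distances, IUPAC signed dihedrals, Bondi van der Waals
  contact classification, change reports between steps;
* **I/O** — standard XYZ, native CSV tables (atoms / pairs / thermo), and a
  documented simplified AIMAll-style `.sum` dialect, with pinned unit
  conversions (1 hartree = 627.5094740631 kcal/mol);
* **synthetic data** — a seeded point-charge/exponential generator and
  planted-energy pathways, so everything is testable without
  quantum-chemistry runs.

All quantum chemistry (optimisation, frequencies, IRC, IQA basin
integration) happens upstream; this package consumes its tabulated output.

## Worked example

The lithium–carbon bond of lithium phenylacetylide, from its printed IQA
components:

```r
library(famsec)
fx <- worked_example_fixtures()

rec <- pair_lookup(fx$nucleophile2$pair_table, "Li27", "C28")
pair_total(rec)
#> [1] -106.9
round(percent_character(rec))
#> cl xc
#> 85 15
```

The Li–C interaction is −106.9 kcal/mol, 85% classical / 15% covalent — a
strongly ionic contact. At the C3-site adduct the same machinery, applied
between lithium and the heterocycle's atoms, recovers the far stronger Li–N4
attraction:

```r
interfragment_energy(fx$adduct3b$pair_table,
                     fragment("Li", "Li27"), fragment("mol1", c("N4", "C3")))
#> E_int(Li, mol1): Vcl -175.8  VXC -9.2  total -185.0 kcal/mol (1/2 pairs)
```

Profiles reference each step against its own composition; the two
nucleophilic-addition intermediates land at +1.1 and −4.9 kcal/mol relative
to the separated reactants, i.e. the C3 product is 6.0 kcal/mol the more
stable:

```r
rep <- build_profile(fx$intermediates$steps, fx$intermediates$thermo)
rep
#> <famsec_rep> 4 steps, terms: E, T = 195.15 K (kcal/mol, relative)
#>          step         role pathway composition    E
#> 1 reactants-a reactant_set   RP-C2         1+2  0.0
#> 2          5a intermediate   RP-C2         1+2  1.1
#> 3 reactants-b reactant_set   RP-C3         1+2  0.0
#> 4          5b intermediate   RP-C3         1+2 -4.9
```

Comparing pathways ranks them by their first barrier and marks
near-degenerate ones comparable:

```r
pathway_compare(rep4, term = "E")   # rep4: a 4-pathway REP table
#> <pathway comparison> term E, tie threshold 0.1 kcal/mol
#>   pathway barrier product_stability rank comparable_group
#> 1   RP-C3    16.0              -4.9    1                1
#> 2   RP-C2    18.0               1.1    2                2
#> 3  RP-C10    36.7               6.0    3                3
#> 4   RP-C5    36.8               6.0    4                3
#> ordering: RP-C3 < RP-C2 << RP-C10 ~ RP-C5
```

A thin command-line wrapper ships under `inst/scripts/famsec`
(`decompose`, `profile`, `geom`, `fixtures`, `report`); see `?famsec_run`.

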