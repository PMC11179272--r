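# pathminer

Chemical-structure-based mining of enzymatic bypass pathways, in R.

## The problem

Metabolic engineers often need a route between two metabolites for which no
known enzyme chain exists — for example, a route from L-DOPA to the unstable
aldehyde DHPAA (3,4-dihydroxyphenylacetaldehyde) that avoids the
peroxide-producing amine oxidase step that bottlenecks benzylisoquinoline
alkaloid production in *E. coli*. Network searches over curated pathways
cannot propose reactions that have never been observed. Structure-based
retrobiosynthesis can: if a known enzyme performs a transformation on one
scaffold, an analogous transformation may be feasible on a related scaffold,
through an intermediate nobody has catalogued.

`pathminer` implements that idea as count-vector arithmetic:

- A molecule *c* is featurized as a non-negative integer vector *f(c)*
  over a fixed schema of atom classes (carbon split by substitution class
  and aromaticity, plain element counts otherwise, hydrogens included) and
  bond types (unordered element pair × bond order, bonds to H included).
- A known reaction (substrate *s* → product *p*) becomes the delta vector
  *r = f(p) − f(s)*; identical deltas are pooled into one reaction feature.
- A query (source → target) asks for multisets of reaction deltas with
  `sum_j x_j r_j = f(target) − f(source)` (exact integer equality),
  `sum_j x_j ≤ k_max`. Solutions are found by an exact branch-and-prune
  integer enumerator, optionally run inside iterative random subsampling of
  the delta index to control large search spaces.
- Each solution is ordered into step sequences whose partial-sum
  intermediates are elementwise non-negative; intermediate vectors are
  matched against known compounds, or carried as *putative* compounds.
- Each step is scored against the known reaction it mimics by count-vector
  Tanimoto similarity `T(a,b) = Σ min(aᵢ,bᵢ) / Σ max(aᵢ,bᵢ)`, averaged over
  the substrate and product sides; a pathway's score is the mean of its
  step scores, and pathways are ranked by score.

Because bond features use bare element pairs, a delta learned on one
scaffold transfers exactly to an analog: the tyrosine → 4HPAA-oxime delta
applied to L-DOPA lands precisely on the DHPAA-oxime vector, which is how
the package proposes a two-enzyme arylacetaldoxime bypass (tyrosine
*N*-monooxygenase, EC 1.14.14.36, then aldehyde oxidase, EC 1.2.3.1)
through an intermediate absent from the knowledge base.

The package also covers the enzyme-screening side of such a campaign:
ortholog thresholding, neighbor-joining phylogeny from distance matrices,
Kyte–Doolittle hydropathy scanning, and N-terminal truncation design for
membrane-anchored P450s — plus monoisotopic/nominal m/z utilities for
MS-based verification of predicted intermediates.

## Worked example

```r
library(pathminer)

kb <- build_demo_kb(42)          # packaged KEGG-like demonstration KB
kb
#> <pathway_kb> 21 compounds (20 searchable), 10 reaction pairs, 6 distinct delta features

res <- mine(kb, "C00355", "C04043", seed = 42)   # L-DOPA -> DHPAA
res
#> <pathway_ranking> C00355 -> C04043: 3 pathway(s)
#>   #1 score 1.0000: 4.1.1.28 > 1.4.3.4
#>   #2 score 0.8617: 1.14.14.36 > 1.2.3.1
#>   #3 score 0.8139: 1.4.3.4 > 4.1.1.28
```

The top pathway is the textbook two-step route (DODC decarboxylation, then
MAO oxidation); both steps are exact known reactions, so it scores 1.0.
Rank 2 is the interesting one — the aldoxime bypass through a putative
intermediate:

```r
res$pathways[[2]]
#> <scored_pathway> C00355 -> C04043, 2 step(s), score 0.8617
#>   1. EC 1.14.14.36 (RP0001)  step score 0.9143  -> putative
#>   2. EC 1.2.3.1 (RP0002)  step score 0.8091  -> C04043
```

Step 1 mimics tyrosine *N*-monooxygenase (L-tyrosine → 4HPAA-oxime) on the
catechol scaffold; its putative intermediate vector equals the
featurization of DHPAA-oxime exactly (the demo holds that structure out of
the searchable index and verifies the match). Step 1 scores higher than
step 2 because L-DOPA/L-tyrosine and the two aldoximes are closer analog
pairs than the aldoxime/ketoxime pair mimicked in step 2 — the same
ordering the similarity scores of the original prediction showed.

Mass utilities confirm the intermediate's identity the way an MS assay
would:

```r
monoisotopic_mz("C8H9NO3", "+H")   # DHPAA-oxime [M+H]+
#> [1] 168.0655
mrm_table()
#>          name   formula precursor_mz product_mz polarity exact_mh nominal_mh
#> 1  reticuline C19H23NO4        330.1     192.00        + 330.1700        330
#> 2 DHPAA-oxime   C8H9NO3        168.1     151.15        + 168.0655        168
```

`run_demo(42)` chains all of the above (knowledge base, mining, holdout
verification, delta-transfer identities, MRM table) into one report, and
`inst/cli/pathminer.R` exposes the same operations as shell subcommands
(`featurize`, `mass`, `demo-kb`, `mine`, `enzyme`, `demo`).

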