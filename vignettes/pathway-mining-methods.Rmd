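---
title: "Count-vector pathway mining: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-vector pathway mining: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathminer)
```

This vignette is the package's own account of the method it implements:
what the model is, what it assumes, which knobs matter, and where the
design was genuinely open and a choice had to be made.

## The model

A molecule is reduced to a non-negative integer **feature vector** over a
fixed schema of atom classes and bond types. A reaction (substrate `s` →
product `p`) is reduced to the **delta vector** `r = f(p) − f(s)`, and a
query transformation (source → target) to the **query delta**
`d = f(target) − f(source)`. The central claim the method exploits is
additivity: if a chain of reactions converts source into target, the
deltas of its steps must sum to `d` *exactly*, feature by feature. The
search therefore enumerates multisets of known-reaction deltas summing to
`d`, orders each multiset into step sequences whose running intermediate
vectors stay elementwise non-negative (a vector with a negative count
describes no molecule), and scores each step by how similar the query-side
substrate/product pair is to the known reaction the delta came from.

The assumptions this rests on:

- **Main-pair chemistry.** Each reaction is a 1:1 substrate→product pair;
  cofactors (O₂, CO₂, H₂O₂, heme) are outside the delta. Feature balance
  therefore holds for the main pair only, not for the full stoichiometric
  equation.
- **Vector equality is the identity criterion.** Two molecules with
  identical feature vectors are indistinguishable to the search. The
  schema is deliberately coarse enough for analog transfer, which means
  isomers sharing all counted features collide; see "Limitations".
- **Similarity predicts transferability.** A step is plausible to the
  extent that its query pair resembles the known pair. That is a heuristic
  ranking signal, not thermodynamics or kinetics.

## The feature schema

The default schema (`feature_schema()`, 282 keys) counts:

- carbon atoms by substitution class — the number of carbon neighbors
  (0–4) — separately for aliphatic (`C.0`…`C.4`) and aromatic
  (`C.ar1`…`C.ar3`) carbons;
- every other element, hydrogen included, as a plain element count;
- bonds as unordered element pair × order (`1`, `2`, `3`, `ar`),
  including one `X-H:1` bond per implicit hydrogen.

Two choices here are load-bearing. First, **bond keys use bare element
pairs**, not substitution-refined atom types. A ketoxime→ketone delta and
an aldoxime→aldehyde delta are then the same vector, so a reaction
observed on acetophenone oxime applies unchanged to an aldoxime — exactly
the analog transfer the demonstration reproduces
(`f(L-DOPA) + [f(4HPAA-oxime) − f(L-tyrosine)] = f(DHPAA-oxime)`, checked
as integer equality in the tests). Refining bond keys by atom class would
make deltas context-specific and kill the transfer. Second, **hydrogens
are counted**: deaminations, oxidations and oxime interconversions change
H counts, and without them deltas would under-determine the chemistry.

The schema is explicit, versioned, and serialized to JSON
(`write_schema()`), so vectors are comparable across runs and across the
command-line tools. The historical platform this method descends from used
a 318-type feature list that was never published in full; this schema is a
documented reconstruction chosen so that the analog-transfer identities
above hold, not an attempt at key-for-key replication. Printed similarity
digits from that platform are therefore matched in *ordering* only, never
digit-for-digit.

Aromaticity is taken from the input notation (lowercase SMILES, MDL bond
order 4) rather than re-perceived, so kekulized and aromatic encodings of
the same ring are different inputs. Fixture structures are all written in
aromatic form.

## Similarity

`tanimoto()` implements the count-vector form
`T(a,b) = Σᵢ min(aᵢ,bᵢ) / Σᵢ max(aᵢ,bᵢ)`; a binary (Jaccard-on-support)
variant is available via `mode = "binary"` for comparison with
fingerprint-style workflows. Conventions for degenerate input: two
all-zero vectors score 1 (the empty molecule is identical to itself);
zero against non-zero scores 0. Step scores aggregate the substrate-side
and product-side similarities by arithmetic mean (default) or minimum
(`step_agg = "min"` for a conservative variant); the pathway score is the
mean of step scores. The mean was chosen as the default because the
method's own description of pathway scoring is an average of reaction
similarities; min is exposed because a single bad side is sometimes a
better rejection signal.

## The combination search

No published formulation of the original search exists beyond "linear
programming over reaction feature vectors with iterative random search
space control", so the solver here is defined from scratch:

- Variables `x_j ∈ {0..c_max}` per delta feature, constraints
  `Σ_j x_j r_j = d` (integer equality per feature) and `Σ_j x_j ≤ k_max`.
- All solutions are enumerated by depth-first branch-and-prune: at row
  `j`, the branch is cut when `‖residual‖₁ > (steps left) × max ‖r‖₁`
  over the remaining rows — a completion bound that is exact for the
  L1 geometry of the problem. Recording solutions at the leaves emits
  each multiset exactly once. A solution cap guards pathological
  instances.
- Identical delta vectors are pooled into one feature before the search
  (each carrying its member reactions), so the enumeration never wastes
  branches on interchangeable reactions.

Correctness is not taken on faith: the test suite compares the enumerator
against an independent brute-force `combn` enumeration on dozens of random
delta instances (40 deltas × 8 features, `k_max` 1–3), and the acceptance
script repeats that comparison on 50 fresh instances per run.

**Random subsampling.** With a realistic database the delta index is far
too large for exhaustive enumeration, so `find_combinations()` defaults to
the iterative random mode: each iteration samples `subset_size` delta
features, runs the exact enumerator on the subset, and pools deduplicated
solutions across `iterations` iterations. The mode is *complete in the
limit* but makes no per-run completeness guarantee; `exhaustive = TRUE`
bypasses it (used by the tests, sensible for any index below a few hundred
deltas). Defaults — 200 iterations of subset 20 — cover the packaged
demonstration index (which is smaller than one subset) many times over;
for larger indexes they are starting points to scale with the index size,
and both are exposed everywhere, including the CLI.

**Other parameters.** `k_max = 3` (pathway length bound; beyond three
steps, ordering cost grows as `k!` and candidate pathways stop being
interpretable as "bypasses"); `c_max = 1` (each reaction used at most once
per pathway — the shortest-bypass use case; raising it permits repeated
chemistry and degenerate cycles, so it is opt-in); `theta = 0.7` (the
similarity threshold applied to per-step *compound candidates*: known
compounds below it are dropped from a putative intermediate's candidate
list). `theta` does **not** filter pathways — the original procedure's
thresholds (0.7/0.8) describe compound selection, and discarding a whole
pathway because one analog step scores low would hide exactly the novel
routes the method exists to find. Pathway-level filtering is left to the
caller on the ranked output.

**Ordering and matching.** Every permutation of a solution multiset is
tried (`k! ≤ 6` at defaults); an order survives if all partial sums are
non-negative. Intermediates are matched against knowledge-base compounds
by **exact vector equality** — a near-match tolerance was deliberately not
offered, because the vector-sum constraint is exact and a tolerant match
would let pathways terminate at a vector that is not actually the target's.
Unmatched intermediates are carried as putative compounds (vector only)
and scored like any other.

**Ranking and ties.** Pathways sort by score (descending), then fewer
steps, then fewer putative intermediates, then the lexicographic
concatenation of step pair ids. The last key is arbitrary but fixed, so a
given knowledge base and seed always produce byte-identical rankings.

## The demonstration knowledge base

`build_demo_kb()` is a first-class, tested generator, not a loose fixture.
It emulates a retrosynthesis knowledge base at desk scale: the eight named
compounds of the aldoxime case study (with their standard structures,
formulas noted in the source for independent checking), the four core
reactions (tyrosine *N*-monooxygenase EC 1.14.14.36, aldehyde oxidase
EC 1.2.3.1, DODC EC 4.1.1.28, MAO EC 1.4.3.4), nine fixed decoy aromatics
wired into six decoy reactions (alcohol/aldehyde/acid oxidations, a
decarboxylative deamination, a ring hydroxylation), and four further decoy
aromatics sampled by seed from a pool of seven. DHPAA-oxime is included as
a **holdout**: its structure ships with the KB but is excluded from
intermediate matching, so the demo can verify that the mined putative
intermediate's vector equals the real structure's featurization without
ever letting the search "see" it. At build time the generator asserts that
no decoy delta equals the query delta, i.e. no decoy solves the case-study
query in one step.

What the fixture does *not* emulate: database scale (thousands of
compounds, ~10⁴ reaction pairs), multi-substrate reactions, reversibility
annotations (all demo pairs are irreversible; reversible pairs get exact
negated deltas when declared), or noisy/erroneous structures. Passing
tests on this KB demonstrate the machinery — exactness, ordering,
scoring, ranking — not retrieval performance at scale. One emergent
behavior is worth noting: the decoy phenethylamine→phenylacetaldehyde pair
has the same delta as MAO at this schema's resolution (the ring hydroxyls
differ, the transformation does not), which is precisely the analog
pooling the schema is designed to produce, and the scorer resolves it by
reporting the best-scoring member reaction per step.

## Enzyme screening

The screening helpers mirror a candidate-selection workflow for the
predicted enzymes:

- `filter_orthologs()` keeps hits with alignment score **strictly** above
  1030 and percent similarity strictly above 39 by default ("over" read as
  exclusive); the score column is treated as an opaque numeric because the
  unit of such thresholds varies by alignment tool.
- `p_distance()` computes mismatch fractions with pairwise gap exclusion;
  `nj_tree()` validates the matrix (symmetry, zero diagonal, unique
  labels) and delegates Saitou–Nei neighbor joining to `ape::nj`, clamping
  negative branch lengths to zero with a warning (they arise only on
  non-additive inputs). Multiple sequence alignment itself is out of
  scope: the module consumes alignments and matrices, it does not build
  them. NJ is exact on additive matrices, and the tests exploit that as an
  oracle: random trees are generated, their path-length matrices fed back,
  and topology plus branch lengths must be recovered (path lengths to
  1e-9).
- `detect_nterm_anchor()` stands in for transmembrane-segment predictors:
  a Kyte–Doolittle windowed mean (window 19 — a transmembrane helix span —
  threshold 1.6, N-terminal search limit 60 residues; all three exposed),
  returning the first maximal run of qualifying windows expanded to
  residue coordinates. It is a standard hydropathy scan, not a replica of
  any particular predictor's proprietary rules; the contract is "find the
  hydrophobic N-terminal anchor". `truncate_nterm()` removes residues
  `1..end` and restores an initiator methionine.

## Mass utilities

`monoisotopic_mz()` sums IUPAC monoisotopic masses (+/− 1.007276 Da for
protonation), rounding half-even to 4 decimals by default, matching
high-resolution MS reporting; `nominal_mz()` uses integer
most-abundant-isotope masses for unit-resolution SIM/MRM settings. The two
are kept distinct on purpose: `mrm_table()` reports instrument transition
settings (constants of the assay) side by side with computed exact masses,
labeled as such, because conflating 168.10 (a quadrupole setting) with
168.0655 (a physical mass) is a classic source of confusion.
`count_db_stereoisomers()` returns `2^k` over stereogenic C=C/C=N double
bonds — termini with two distinguishable substituents, the lone pair
counting as one on divalent nitrogen — which is how an aldoxime comes to
have exactly two (*E*/*Z*) isomers, visible as twin chromatogram peaks in
practice. Ring-internal double bonds are excluded.

## Determinism and problem sizes

Every stochastic element (decoy sampling, search subsampling, test
instances) flows through explicit integer seeds, and seeded runs are
byte-identical, fixture files included. The test and acceptance workloads
use desk-scale sizes — a ~20-compound knowledge base, 50 random
40×8 solver instances, trees of 4–8 taxa — chosen so the whole suite runs
in seconds while still exercising every code path; all scale knobs are
ordinary function arguments.

## Known limitations

- Feature vectors are not injective: isomers identical in all counted
  features collide, so "exact vector match" means "indistinguishable at
  schema resolution", not "same molecule".
- The SMILES parser covers the organic subset, brackets
  (charge/H-count/isotope prefix), rings and branches; it rejects
  disconnected components and ignores tetrahedral stereo marks.
  Aromaticity is notation-trusted, not perceived.
- No thermodynamics, kinetics, atom mapping, or flux reasoning; ranking
  is purely structural similarity.
- The random search mode trades completeness for tractability; use
  exhaustive mode when the delta index allows it.
- Wet-lab outcomes of the case study (titers, fold-improvements) are
  experimental results and are outside what this package can or does
  reproduce; the demo reproduces the *prediction*, its internal
  consistency checks, and the identification arithmetic.
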