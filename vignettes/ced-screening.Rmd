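---
title: "Two-tier screening of proteins for celiac disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier screening of proteins for celiac disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedscreen)
```

## The screening problem

Celiac disease (CeD) is driven by gluten-derived peptides — fragments of
the proline/glutamine-rich prolamin and glutelin seed-storage proteins of
wheat, barley, rye and related Pooideae grasses — that survive digestion,
are presented on HLA-DQ2.5/DQ8, and activate CD4⁺ (rarely CD8⁺) T cells or
trigger innate epithelial toxicity. Many causative peptides act in their
transglutaminase-2 (TG2) deamidated form, in which specific glutamines are
converted to glutamic acid. A novel food protein is a CeD concern if it
contains such a peptide verbatim, or if it is similar enough to a known
CeD-associated protein that it plausibly harbors unreported epitopes.

`cedscreen` turns that reasoning into a deterministic decision procedure:

* **Tier 1 — exact peptide match.** The query is scanned for every exact
  occurrence (overlaps and nestings included) of every database peptide.
  Any hit ⇒ `probable_risk`. This tier is the most definitive: identity to
  even one documented causative peptide is direct evidence.
* **Tier 2 — panel alignment.** Queries without exact hits are aligned
  locally against each representative CeD protein. If any alignment
  simultaneously reaches identity ≥ 45 %, expectation value E < 10⁻¹⁴ and
  overlap ≥ 100 columns ⇒ `possible_risk`; else
  `no_significant_similarity`. The tier insures against the incompleteness
  of the peptide catalog (roughly a fifth of Pooideae prolamins carry no
  currently documented peptide) and against small mutations that break an
  exact match without abolishing reactivity.

Either flag means "test further with CeD-specific T-cell assays", never a
clinical judgement; the absence of a flag is not a safety certificate.

## Decision thresholds and boundary semantics

`ced_thresholds()` defaults to the guideline values 45 % / 10⁻¹⁴ / 100 AA.
The three criteria are **conjunctive**: safe-sequence characteristics are
naturally stated disjunctively (low identity, *or* large E, *or* short
overlap), and by De Morgan a risk flag requires all three to fail to hold
in their safe direction. Boundary cases are resolved as: identity ≥ 45.0
passes, E strictly < 10⁻¹⁴ passes, overlap ≥ 100 passes. The overlap
boundary is genuinely ambiguous between "greater than" and "at least" in
the source guidance; we chose ≥ 100 (the inclusive reading) and expose it
as a parameter. A fourth, unquantified safe-sequence characteristic —
"aligned with many gaps" — is surfaced as the gap fraction in every
verdict rationale but never used in the verdict itself.

## Alignment model

Tier 2 uses optimal Smith–Waterman local alignment under affine gap
penalties, computed by `Biostrings::pairwiseAlignment()` behind the
`local_align()`/`align_panel()` surface. Defaults are BLOSUM50 with gap
open −10 and extend −2 (a gap of length L costs 10 + 2L) — the classic
parameterization of full-length FASTA-style protein searches. Because the
representative panel is small (tens of proteins), exhaustive optimal DP is
affordable and no heuristic k-tuple stages are needed. The test suite
cross-checks scores against an independent brute-force Gotoh dynamic
program on hundreds of seeded random pairs.

Reported statistics follow the conventions of full-length FASTA reports:

* `overlap_len` — all alignment columns, gap columns included;
* `identity_pct` — identical aligned pairs / `overlap_len` × 100;
* `gap_columns` — columns with a gap in either row;
* spans — 1-based closed intervals `[start, end]` on query and subject.
  (1-based closed coordinates are used throughout the package, matching
  the R/Bioconductor convention.)

When several tracebacks tie at the optimal score the reported alignment is
whichever the aligner deterministically produces; identical inputs always
yield identical output.

### E-values

`evalue_karlin_altschul()` computes E = K·m·n·e^(−λS), with m the query
length and n the **total residue count of the searched panel**, so that E
scales with search size: doubling the panel doubles E at fixed score.
Defaults λ = 0.090, K = 0.021 are rough literature values for gapped
BLOSUM50 scoring. We deliberately do not attempt to reproduce the
empirically regressed E-values of any particular FASTA release bit-exactly;
published E-scores of specific alignments (e.g. 10⁻⁷⁸ magnitudes for
near-identical gliadin alignments) are meaningful here only as orders of
magnitude, and the package's own E-values behave correctly under the
closed-form limits (E = K·m·n at S = 0, monotone decreasing in S, linear
in n) that the tests assert. Both parameters are configurable via
`align_config()`.

## Deamidation model

TG2 preferentially deamidates glutamine in the Q-X-P configuration (X any
residue but proline). `find_deamidation_sites()` reports every such
3-residue window; `deamidate()` applies Q→E at chosen sites;
`enumerate_deamidated()` applies **all non-empty subsets** of sites
(deterministic order: subset size, then lexicographic site tuple),
because epitope catalogs store multiple partially deamidated forms of the
same native peptide, not a single fully deamidated product. The default
cap of 4096 variants guards pathological Q/P-rich inputs. The model is
purely positional — no TG2 kinetics, no spacing rules beyond QXP.

`scan_efsa_motif()` implements the coarser 4-mer Q/E-X1-P-X2 screen from
the EFSA GMO allergenicity guidance. The guidance does not state whether
X1/X2 may be proline; we treat both as unconstrained and note that the QXP
sites are therefore (window-permitting) a subset of the EFSA hits with Q
at position 1 and X1 ≠ P. Exact matching never auto-deamidates the query;
`enumerate_deamidated()` is available for exploratory scans of query
variants.

## Peptide database contract

Peptide records carry `sequence`, `form` (native/deamidated), `evidence`
(immunogenic/toxic), optional `t_cell` (CD4/CD8/none) and references.
Records shorter than nine residues are rejected with a distinct reason —
a peptide below the 9-mer MHC class II binding core is considered unable
to bind and activate T cells. `X` is forbidden in peptides (an epitope
claim requires exact residues) but allowed in queries, where it matches
nothing and scores as the matrix's X column in alignments. Sequence is the
identity key: duplicate rows merge, unioning references. The delimited
table dialect (comma or tab) is auto-detected from the header line.

## What the synthetic generator emulates

The original validation of this screening design used thousands of NCBI
sequences in four groups: (I) Pooideae prolamins with/without known
peptides, (II) non-Pooideae grass prolamins, (III) dicot prolamin-like
proteins, (IV) unrelated proteins. Those snapshots are not reproducible at
desk scale, so `make_toy_assets()` generates a structurally analogous,
fully deterministic replacement:

* prolamin-like sequences = random flanks (20 AA each, average globular
  composition) around 25–35 noisy copies (5 % per-position substitution)
  of the repeat unit `PQQPFPQQ`, mimicking gliadin repeat architecture and
  guaranteeing > 30 % Q+P content;
* a database of 20+ peptides: the three literature-documented example
  peptides, their predicted deamidated variants, and planted synthetic
  Q/P-rich peptides (9–15-mers from the same repeat grammar);
* a panel of six prolamin-like representatives carrying the planted and
  reference peptides;
* query groups: `group_I` (carry database peptides ⇒ probable risk by
  construction), `group_Ib` (panel homologs mutated at 2 % and then
  *ablated* of every exact match ⇒ high-identity possible risk),
  `group_II`/`group_III` (repeat proteins from divergent grammars —
  `MQNSLALANS` at 10 % noise and `SESTVKDWMR` at 15 % — chosen so panel
  identity stays below the 45 % criterion), `group_IV` (i.i.d. background
  sequences, 80–400 AA).

Group sizes (4/2/3/3/4) are kept small so a full grouped classification
runs in seconds; the group report reproduces the published table format
(per group: exact-peptide content and the three best alignments as
overlap, subject length, % identity, E-score), not its NCBI-survey
numbers. What passing these panels shows is that the decision logic and
its thresholds behave correctly on sequences with the intended
architecture; it does not show recall on real proteomes — real prolamins
are more heterogeneous in repeat unit, length and composition than the
generator, and real homolog groups are not cleanly separated by
construction.

## In-silico substitution validation

`ablate_matches()` reproduces the alanine-substitution experiment used to
validate the alignment tier: substitute residues until the exact tier is
silent, then re-align the mutant to its original. Position choice is a
greedy cover (substitute the position under the most remaining hits,
leftmost on ties, re-scan after every substitution so newly created
matches are caught); greedy may exceed the true minimal cover, so tests
assert ablation success and the identity bound, not minimality. A
`positions` override lets a user script a published substitution profile
against a real sequence of their own. On a 290-residue protein, 13
substitutions leave 95.5 % full-length identity with zero gap columns —
still far above the 45 % criterion, which is exactly why the alignment
tier catches epitope-breaking point mutants that defeat exact matching.

## Numerical and degenerate-input choices

* Alignments with no positive-scoring pair return an empty result (score
  0, overlap 0, E = K·m·n) rather than an error.
* `evalue_karlin_altschul()` rejects non-positive λ or K as configuration
  errors; raw scores must be non-negative.
* Ties in `align_panel()` ordering are broken by ascending E, then
  descending identity, then subject id — batch output is fully
  deterministic.
* All generator randomness flows through one integer seed; the RNG state
  of the caller is saved and restored.
* Sequences shorter than the motif windows yield empty hit tables, not
  errors; empty FASTA input and empty databases are errors.

## Problem sizes used in tests

The bundled suite runs the exact-match oracle comparison on 500+200 seeded
random instances, the alignment-vs-DP comparison on 340 seeded pairs of
length ≤ 30, 100-draw simulations for the unrelated-group false-positive
rate, and full grouped classifications of the synthetic assets — about
2,800 assertions in roughly a minute on one core.

## Known limitations

* E-values are approximate; do not compare them across scoring systems.
* The deamidation model is positional only and enumerates subsets, which
  is exponential in site count (capped, with a warning).
* Exact matching is case- and residue-exact; one-mismatch or HLA
  binding-core (anchor position) modeling is out of scope.
* The screening thresholds were calibrated on seed-storage prolamin
  families; applying them to short queries (< 100 AA) makes the overlap
  criterion unsatisfiable by design, and such queries can only be flagged
  by the exact tier.
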