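# cedscreen

Celiac disease (CeD) is an autoimmune enteropathy triggered in genetically
susceptible (HLA-DQ2/DQ8) individuals by digestion-resistant peptides from
the prolamin and glutelin storage proteins of wheat, barley, rye and other
Pooideae grasses. Before a novel food protein — for instance one expressed
in a GM crop — reaches consumers, regulators expect an assessment of whether
it could elicit CeD. `cedscreen` implements that assessment as a two-tier
sequence-screening pipeline for risk assessors and bioinformaticians:

1. **Exact peptide tier.** Every query protein is scanned for exact
   occurrences of known CeD-associated peptides, including their predicted
   transglutaminase-deamidated forms (Q→E at Q-X-P sites, X ≠ P). A single
   occurrence flags the query as `probable_risk`.
2. **Alignment tier.** Queries with no exact hit are locally aligned
   (Smith–Waterman, affine gaps, BLOSUM50 with gap open −10 / extend −2)
   against a panel of representative CeD proteins. An alignment with
   identity ≥ 45 % **and** expectation value *E* < 10⁻¹⁴ **and** overlap
   ≥ 100 AA (all three, conjunctively) flags `possible_risk`; otherwise the
   verdict is `no_significant_similarity`.

Percent identity counts identical residue pairs over *all* alignment
columns, gaps included. The expectation value follows the Karlin–Altschul
form *E = K·m·n·e^(−λS)*, with *n* the total residue count of the searched
panel; λ and K defaults are documented approximations for gapped BLOSUM50
scores, so E-values are order-of-magnitude guides, not bit-exact
reproductions of any specific search engine. Verdicts are screening flags:
flagged proteins should go on to CeD-specific CD4/CD8⁺ T-cell assays, and
`no_significant_similarity` is not a safety certificate.

The package also provides the QXP deamidation-site predictor and
combinatorial variant enumerator, the coarser EFSA Q/E-X1-P-X2 4-mer motif
scan, an in-silico substitution validator that ablates every exact peptide
match from a protein and re-aligns it, and a seeded synthetic generator of
prolamin-like sequences, peptide databases and grouped validation panels so
that the entire pipeline is testable offline.

## Worked example

A small peptide table (the three literature-documented gluten peptides —
the 33-mer α2-gliadin CD4⁺ epitope region, the 13-mer innate/toxic gliadin
peptide, the CD8⁺ peptide p123–p132 — plus their ten predicted deamidated
variants) and synthetic panel/query FASTA files ship with the package:

```r
library(cedscreen)

db    <- read_peptide_table(system.file("extdata", "example_peptides.tsv",
                                        package = "cedscreen"))
idx   <- build_peptide_index(db)
panel <- read_fasta(system.file("extdata", "synthetic_example_panel.fasta",
                                package = "cedscreen"))
qry   <- read_fasta(system.file("extdata", "synthetic_example_queries.fasta",
                                package = "cedscreen"))
batch <- classify_batch(qry, idx, panel)
batch
#> CeD risk screening of 3 quer(ies):
#>   probable_risk              1
#>   possible_risk              1
#>   no_significant_similarity  1
batch$verdicts[, c("query_id", "category", "best_identity_pct",
                   "best_overlap_len", "best_e_score")]
#>       query_id                  category best_identity_pct best_overlap_len best_e_score
#> 1  gI_query_01             probable_risk                NA               NA           NA
#> 2 gIb_query_01             possible_risk              97.1              272     3.98e-79
#> 3 gIV_query_01 no_significant_similarity              21.3               47     1.71e+02
```

The first query contains a database peptide verbatim, so the exact tier
short-circuits to `probable_risk` and the panel is not consulted. The
second is a prolamin-like homolog with every exact match removed: it still
aligns at 97 % identity over 272 columns with a vanishing E-value, meeting
all three alignment criteria (`possible_risk`). The third, an unrelated
background protein, aligns only weakly (21 % over 47 columns, E ≫ 1).

Deamidation-site prediction on the 33-mer:

```r
find_deamidation_sites("LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF")
#>   start motif     kind
#> 1    10   QLP QXP_site
#> 2    17   QLP QXP_site
#> 3    24   QLP QXP_site
```

A command-line wrapper with subcommands `exact`, `motifs`, `align`,
`classify`, `mutate` and `simulate` is installed at
`system.file("cli", "ced-screen.R", package = "cedscreen")`; all of its
output coordinates are 1-based closed intervals.

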