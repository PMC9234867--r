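Package: cedscreen
Title: Celiac Disease Risk Screening of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-tier bioinformatics screening of query proteins for celiac
    disease (CeD) risk. Tier one finds exact occurrences of CeD-associated
    peptides (native and predicted transglutaminase-deamidated forms) within
    query sequences; tier two performs full-length local alignment against a
    panel of representative CeD proteins and applies conjunctive identity,
    expectation-value and overlap-length criteria to flag possible risks.
    Includes QXP deamidation-site prediction, the EFSA Q/E-X1-P-X2 motif scan,
    an in-silico alanine-substitution validation procedure, and a deterministic
    synthetic generator of prolamin-like sequences, peptide databases and
    grouped validation panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
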