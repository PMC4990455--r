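Package: savlink
Title: Linking Molecular-Effect Predictions of Protein Variants to Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how predicted molecular effects of single
    amino acid variants (SAVs) relate to Mendelian disease. Provides readers
    for protein sequences, curated variant tables, prediction score tables
    and substitution matrices; validation of curated variant annotations
    against sequences (match / +1-shift / mismatch attrition); cross-species
    variant transfer through global affine-gap alignment with coordinate
    liftover; enumeration of amino-acid substitutions reachable by a single
    nucleotide change; per-position conservation profiles (information
    content in bits) with conservation-matched null-position sampling; binary
    effect/neutral calls from score tables via configurable cutoffs;
    effect-fraction summaries with bootstrap intervals and pairwise method
    agreement; and a synthetic-data generator producing protein families,
    planted disease variants, ortholog pairs and predictor scores with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
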