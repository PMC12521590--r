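Package: degradomics
Title: Mining Endogenous Protein Termini from Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for degradomics analysis of shotgun label-free
    proteomics experiments: calling endogenous N- and C-termini from
    semi-tryptic peptide reports, classifying mature versus neo termini
    against signal-peptide annotation, class-specific quantile
    normalization, regression-tree imputation of missing intensities,
    empirical-Bayes moderated t-tests with Storey q-values, cleavage-window
    residue-preference profiling (Schechter-Berger P5-P5'), known
    cleavage-site annotation and protease enrichment, and a seeded
    synthetic degradome generator for end-to-end validation by recovery of
    planted cleavage events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    rpart,
    withr,
    jsonlite,
    tools,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
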