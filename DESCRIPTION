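Package: metresist
Title: Dose-Response, Drug Synergy, Fusion-Transcript and Copy-Number
    Analyses for Kinase-Inhibitor Resistance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for characterising acquired resistance to
    targeted kinase inhibitors in cell-line models. Converts viability-plate
    luminescence into tumour-cell growth inhibition (TGI), fits
    four-parameter logistic dose-response curves with censored-IC50
    reporting, scores drug-combination matrices under Bliss independence
    (ΔBLISS surfaces and maximal-synergy dose windows), detects fusion
    transcripts from paired-end reads via discordant-pair counting, de novo
    junction-contig assembly and split-point localisation, computes per-base
    RBM (reads per base per million reads) coverage and region folds,
    segments copy-number log2-ratio tracks with breakpoint-bisected gene
    annotation, and preprocesses protein-array intensity matrices. A
    synthetic-data module generates all inputs with recorded ground truth
    for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
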