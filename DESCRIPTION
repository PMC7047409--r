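Package: finregen
Title: Epigenomic Analysis of Zebrafish Fin Regeneration
Version: 0.1.0
Authors@R:
    person("finregen", "maintainers", email = "finregen@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for multi-omics analysis of
    regenerating zebrafish fin tissue: whole-genome bisulfite differential
    methylation with a beta-binomial Wald test and empirical replicate-null
    false-discovery calibration, Tn5 insertion-based chromatin accessibility
    and differential accessibility, negative-binomial differential
    expression, classification of candidate regeneration enhancers,
    footprint-based gene-regulatory-network construction, and CRISPR gRNA
    scoring. Ships a seeded synthetic multi-omics generator with a
    ground-truth ledger so every stage can be validated by planted-signal
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
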