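Package: agemeth
Title: Multi-Tissue Age-Associated DNA Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting age-associated CpG
    methylation (ageCGs) across human tissues. Implements two-channel
    methylation-array preprocessing (negative-control background
    subtraction, detection p-values, beta-score computation without the
    vendor +100 correction, missingness filtering, empirical-Bayes batch
    normalization), per-CpG linear regression of methylation on age with a
    gender covariate and Benjamini-Hochberg FDR, CpG island/shore/other
    context statistics, cross-tissue overlap permutation tests,
    gene-expression enrichment tests, a targeted bisulfite-sequencing
    methylation caller with in-silico conversion and quality/depth
    filtering, and a regional linear mixed model with continuous-distance
    AR(1) correlation for widespread age effects. Ships a synthetic-data
    generator with known truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nlme,
    sva,
    data.table,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
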