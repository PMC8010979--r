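Package: comethmed
Title: Co-Methylation Network Mediation of Early-Life Exposure Effects on
    Brain Region Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline linking a childhood family
    emotional health score to fronto-limbic brain region volumes through
    saliva co-methylation module eigengenes. Provides methylation array
    preprocessing (M-value transform, quantile normalization, probe
    filters, cross-tissue correlation filter), reference-free cell-type
    deconvolution, weighted co-methylation network construction with
    topological overlap dissimilarity and module eigengenes, gated
    association arms with Benjamini-Hochberg control, nonparametric
    bootstrap mediation with full/partial mediator classification, and
    probe-count-aware gene-set enrichment. A seeded synthetic-data
    generator with planted modules and mediation effects makes every
    stage testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
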