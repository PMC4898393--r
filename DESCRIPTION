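Package: cghcnv
Title: Copy Number Variant Calling and Verification from Array CGH and
    Read Depth
Version: 0.1.0
Authors@R:
    person("CNV", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A pipeline for genome-wide copy number variant (CNV) surveys
    built around array comparative genomic hybridization (CGH) segment
    calls. Segment calls are classified as true or false CNVs with a
    logistic model trained on trio-validated calls (known positives) and
    self-self hybridization calls (known false positives), filtered with
    chromosome-aware rules, and merged across animals into CNV regions
    (CNVRs). Copy number is independently called from sequencing read
    depth via GC correction and a constrained normal/half-normal mixture
    model, enabling cross-platform verification that accounts for CNVs
    carried by the reference animal. Spatial clustering of CNVRs is
    tested against a uniform-placement null, and gene-overlap enrichment
    against a Monte-Carlo randomization null. A synthetic-data module
    generates truth-known inputs (trio-structured CGH calls, GC-biased
    depth tracks over planted copy-number regions, lower-sensitivity
    platform call sets) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
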