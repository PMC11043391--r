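Package: screenkit
Title: Analysis of Pooled and Arrayed CRISPR Drug-Resistance Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of CRISPR drug-resistance screening studies in
    cancer cell lines: negative-binomial per-guide enrichment testing and
    alpha-RRA (robust rank aggregation) gene-level scoring for pooled screens,
    integration of hit tables across screens into core resistance genes,
    scoring of arrayed high-content nuclear-translocation screens (cell
    filtering, nuclear:cytoplasmic ratios, two-point plate normalization, hit
    calling), hypergeometric gene-set and transcription-factor enrichment with
    pre-ranked enrichment scores and single-cell signature (module) scores,
    and immunohistochemistry H-scoring. Ships synthetic-data generators with
    planted ground truth so every stage can be exercised and calibrated
    without access to raw screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    DESeq2,
    fgsea
Config/testthat/edition: 3
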