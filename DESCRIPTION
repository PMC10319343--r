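Package: seedcycle
Title: Seed Priming Proteomics and Physiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for label-free quantitative proteomics and
    seed physiology experiments along a seed rehydration-dehydration
    (hydropriming plus dry-back) cycle. Implements missing-value-aware
    differential protein abundance with pooled-variance t-tests, modified
    robust z-score normalization and pseudo fold-change imputation for
    proteins detected in only one condition; preranked gene-set enrichment
    on t-statistic rankings with permutation-based normalized enrichment
    scores; hypergeometric over-representation analysis; seed germination
    indices (germinability, mean germination time, germination rate and
    velocity coefficients, uncertainty, synchrony, T50); comet-assay damage
    scoring in arbitrary units; efficiency-corrected qPCR relative
    expression (Pfaffl method) from raw amplification curves; and
    transcript-protein fold-change correlation. A synthetic-data module
    generates every input with the statistical structure the analysis
    assumes, so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
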