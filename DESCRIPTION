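Package: concordAD
Title: Cross-Species Transcriptomic Concordance Scoring for Mouse Models of
    Late-Onset Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-variant transcriptomic effects from panel-based
    (NanoString-style) mouse brain expression counts via housekeeping
    normalization, empirical-Bayes batch correction, and an additive per-gene
    multiple regression with a nested genetic-background control hierarchy,
    then scores each perturbation's human-disease relevance by Pearson
    correlation of its effect vector against human co-expression-module and
    disease-subtype log2 fold-change signatures. Includes preranked gene-set
    enrichment (weighted Kolmogorov-Smirnov running sum with gene-permutation
    null), directional-coherence gene extraction, hypergeometric
    overrepresentation testing with Benjamini-Hochberg FDR control,
    correlation dot-plot reporting, and a fully seeded synthetic-data
    generator that emulates the panel experiment and human signatures with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    sva
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
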