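Package: proteonet
Title: Differential Proteomics with Network Propagation and Term Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for factorial TMT proteomics of
    nutrient-signaling interventions: peptide-level log2/z rescaling,
    detection filtering, k-nearest-neighbour imputation, empirical-Bayes
    moderated t-statistics for named factorial contrasts, propagation of
    fold changes over a high-confidence protein-protein interaction
    network, quantile/degree node selection, one-sided Fisher term
    enrichment with signed significance scores, rule-based classification
    of S6K-dependent responses, and cross-dataset concordance aggregation.
    Includes a synthetic-data generator with planted network modules and
    enriched terms so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
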