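Package: prognet
Title: Network-Smoothed Feature Selection and Survival Stratification
    for Prognostic Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("prognet", "developers", email = "prognet@example.org",
           role = c("aut", "cre"))
Description: Discovers prognostic gene signatures from expression data by
    smoothing per-gene differential t-statistics over a protein-protein
    interaction network with a p-step random-walk graph kernel, gating
    candidates by log fold change, and validating selections with repeated
    stratified cross-validation scored by AUC. Downstream refinement covers
    weighted co-expression modules (soft-threshold scan, topological overlap,
    eigengenes, module-trait correlation), minimum-spanning-tree hub
    extraction, and median-split Kaplan-Meier survival stratification with a
    Gehan-Wilcoxon test. Ships a seeded synthetic-data generator that plants
    a connected differential subnetwork with block-correlated co-expression,
    batch shifts and expression-linked survival, plus a command-line
    interface for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    limma,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
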