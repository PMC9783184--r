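Package: adipostage
Title: Lipid Class Composition, Batch-Corrected Differentiation Staging, and
    Pathway Enrichment for Adipocytic Tumor Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for comparing well-differentiated and
    dedifferentiated liposarcoma multi-omics profiles. Parses shorthand lipid
    species names (e.g. "TG(16:0/16:1/18:3)", "PC(34:2e)") into structured
    records, aggregates species to lipid classes, and runs per-feature
    differential tests with volcano-style gating, PCA, and set-overlap
    summaries. Implements parametric empirical-Bayes (ComBat-style) batch
    correction so that tumor, normal-tissue, and stromal-vascular-fraction
    (SVF) expression matrices can be staged against an adipogenic
    differentiation time course via a Euclidean-distance similarity score,
    and provides preranked gene-set enrichment (ES/NES with a gene-label
    permutation null). A synthetic-data generator with full ground-truth
    bookkeeping makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    fgsea,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
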