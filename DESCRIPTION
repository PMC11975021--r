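Package: pbmultiome
Title: Pseudobulk Case-Control Analysis of Longitudinal Single-Cell Multiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal case-control analysis of single-cell and
    single-nuclei multiomic cohorts (snRNA, scRNA, snATAC). Implements
    lineage-collapsed pseudobulk aggregation with per-million normalization,
    per-feature Fisher observed/expected differential testing with
    Benjamini-Hochberg false discovery control, cross-data-layer replication
    classification, cis peak-gene linking within 1 Mb of transcription start
    sites with orthogonal-layer validation, genotype-dosage Spearman QTL
    scanning, adjacent differential-peak clustering statistics, directional
    transcription-factor motif representation tests, and autoantibody-endotype
    subgroup analyses. Ships a synthetic multi-layer cohort generator with
    planted effects so the full pipeline is testable without controlled-access
    data.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
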