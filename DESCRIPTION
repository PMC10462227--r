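Package: plasmapipe
Title: Synthetic Single-Cell Multiome Cohorts and a Plasma-Cell Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Generates synthetic single-cell multiome (RNA + ATAC) cohorts of
    plasma-cell disorders with known ground truth, and provides a tested
    analysis pipeline over them: per-cell quality control, iterative
    marker-percentile removal of non-plasma contaminant clusters, joint
    RNA+ATAC graph clustering, reference-based copy-number inference from
    expression with arm-level event calling and clone assignment, per-patient
    cluster-proportion association with disease stage and genomic events,
    Wilcoxon differential expression and gene-level chromatin accessibility
    with Benjamini-Hochberg control, signature intersections with Fisher
    overlap tests, and transcription-factor promoter-peak percentile analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
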