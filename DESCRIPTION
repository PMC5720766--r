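Package: epicompress
Title: Linear Redundancy Analysis of Epigenetic and Regulatory Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binned, quantile-scaled enrichment matrices for epigenetic
    and regulatory marks (histone modifications, DNA methylation, transcription
    factors, coregulators, chromatin remodelers) around gene features from
    signal tracks and gene annotations, then quantifies the redundancy among
    the marks. Every mark is predicted from the remaining marks with linear
    models under 10-fold cross-validation, models are transferred across cell
    lines to separate generally applicable from cell-line-specific association
    rules, gene expression is modeled from promoter-bin enrichments with linear
    and additive hinge-spline (MARS) regressions, and marks are ranked by their
    information content through greedy forward selection. A synthetic-world
    generator with planted latent-factor correlation structure provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
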