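Package: bopscan
Title: Region-Centric Differential DNA Methylation Analysis for Family-Based Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a block-of-probes (BOP) workflow for Illumina 450k-style
    DNA methylation arrays in trio cohorts: probe classification by CpG-island
    relation and gene context, grouping of CpG-dense probes into blocks,
    detection p-value quality control, reference-based leukocyte deconvolution
    by constrained projection, covariate-adjusted sliding-window MANOVA and
    site-level ANOVA differential methylation scans with Benjamini-Hochberg
    correction, chromosome-level distribution and enrichment tests, and a
    delta-beta based epigenetic signature selection with clustering and
    multidimensional scaling outputs. A synthetic cohort generator with planted
    region effects, group-dependent cell composition and beta-distributed noise
    makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    ape,
    car,
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
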