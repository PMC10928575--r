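Package: immunoEAA
Title: Immune-Cell Composition and Epigenetic Age Acceleration in Blood
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how blood immune-cell composition drives
    epigenetic age acceleration (EAA). Provides reference-based cell-type
    deconvolution of DNA methylation beta values by constrained least
    squares over a 12-cell immune reference, evaluation of linear
    methylation clocks with library-level quality-control masking,
    construction of residual and difference EAA and of intrinsic EAA
    (IEAA) adjusted for six or eleven cell types, per-cell and mutually
    adjusted association models with age-group z-scoring and
    Benjamini-Hochberg FDR control, partial and additional R-squared
    variance decomposition, composition PCA quality control, and a
    matched case/control confounding study. A synthetic-data module
    generates reference libraries, cohorts with age- and disease-dependent
    composition plus intrinsic age drift, and planted clocks with known
    intrinsic fractions, so every downstream stage has a ground-truth
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
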