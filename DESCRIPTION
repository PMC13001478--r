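Package: omiflim
Title: Single-Cell Optical Metabolic Imaging from Fluorescence Lifetime Decays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free optical metabolic imaging (OMI)
    of immune cells by fluorescence lifetime imaging microscopy (FLIM).
    Simulates time-correlated single photon counting (TCSPC) decay cubes from
    ground-truthed multi-cell scenes; fits biexponential decays with
    instrument-response reconvolution by Poisson maximum likelihood; extracts
    per-cell OMI feature tables (NAD(P)H and FAD lifetime components, optical
    redox ratio, cell area) with quality-control filters; and provides the
    downstream statistics used for single-cell immune phenotyping: Cohen's d
    effect sizes, coefficient-of-variation heterogeneity, Ward hierarchical
    clustering, and balanced one-vs-rest random-forest classification with
    full ROC/AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    tiff,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
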