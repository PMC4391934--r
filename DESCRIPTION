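Package: ki67ck
Title: Quantitative Multispectral Ki67/Cytokeratin Imaging Analysis with
    Survival Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative in situ multiplexed fluorescence imaging
    of the Ki67 proliferation marker against a cytokeratin (CK) tumour mask.
    Simulates or ingests 21-band multispectral image cubes (450-650 nm),
    unmixes each pixel into CK, Ki67 and autofluorescence components by
    non-negative least squares, aggregates per-core Ki67 sum, CK sum and the
    Ki67/CK ratio over six fields, dichotomises biomarkers by the best-P
    log-rank cut-point with Miller-Siegmund correction for the implicit
    multiple testing, and evaluates prognostic value with Kaplan-Meier
    curves, log-rank tests, Cox proportional-hazards models and ROC/AUC.
    Includes a synthetic-data module generating spectral scenes with known
    ground truth and patient cohorts with proportional-hazards outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
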