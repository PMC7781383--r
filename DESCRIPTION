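Package: aptamarkers
Title: Aptamer qPCR Panels for Predicting Brain Amyloid Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of aptamer-based plasma screening
    ("Aptamarkers") for binary brain amyloid status: selection-library
    FASTQ counting and candidate-aptamer selection, derivative-threshold
    Cq calling from raw qPCR amplification curves, pairwise Cq-ratio
    feature engineering, sparse partial least squares discriminant
    analysis with soft-thresholded loadings, a nearest-zero z-score
    decision rule, and repeated hold-out cross-validation.  Includes a
    synthetic-data generator emulating the cohort structure the analysis
    assumes (class-dependent Cq shifts, sigmoid amplification curves,
    class-enriched selection libraries), so the full pipeline can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
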