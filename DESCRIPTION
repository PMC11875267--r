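Package: cfmethms
Title: Plasma Cell-Free DNA Methylation Biomarker Analysis for Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for low-coverage plasma cell-free DNA (cfDNA)
    whole-genome bisulfite sequencing in multiple sclerosis cohorts.
    Implements per-CpG beta-binomial differential methylation with neighbour
    p-value combination and differentially methylated region (DMR) calling;
    region feature construction (missingness filtering, kNN imputation, SVD
    with elbow selection) and chromatin-state enrichment against matched
    random intervals; fragment-level U/X/M tissue-of-origin deconvolution
    with a sequencing-coverage power simulation; a longitudinal linear
    mixed-model screen for prognostic regions with a methylation-based
    progression risk score (MBPRS), progression-free survival stratification
    and matched-interval permutation controls; and a leakage-safe
    cross-validated classification harness. Ships a synthetic-cohort
    generator reproducing the statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    e1071,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    pROC,
    optparse
Config/testthat/edition: 3
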