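Package: preemiexpr
Title: Transcriptomic Biomarker Discovery for Preterm Respiratory Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peripheral-blood CD8+ T-cell RNA-seq
    biomarker discovery in preterm infants. Implements conditional
    upper-quartile count normalization with prevalence-based gene and
    subject filters, neonatal oxygen-utilization metrics (effective FiO2
    and cumulative oxygen AUC) with bronchopulmonary dysplasia (BPD) and
    post-prematurity respiratory disease (PRD) outcome labeling, three
    univariate differential-expression screens (rank correlation with
    oxygen exposure, a resampling Wilcoxon test on counts, and a
    gestational-age-adjusted logistic likelihood-ratio test), a screened
    principal-components BPD classifier, and a pathway-eigengene logistic
    forward-selection PRD classifier, both evaluated by nested
    cross-validated ROC/AUC. A negative-binomial cohort simulator with
    planted signal genes, correlated pathway blocks, and oxygen-exposure
    traces supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
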