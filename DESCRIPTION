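Package: bloodtme
Title: Inferring Tumor Microenvironment Immune Status from Blood Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step framework for liquid-biopsy immuno-oncology: (1) learn
    per-cell-type linear maps from peripheral-blood immune cell fractions and
    pseudo-bulk gene expression to their tumor-microenvironment (TME)
    counterparts, using six compact candidate models (blood predictor alone or
    paired with one clinical covariate) fit with elastic-net regularization
    under replicated 80/20 cross-validation; (2) screen blood-inferable TME
    signatures (immune-checkpoint-gene expression, cell fractions, and
    enumerated cell-fraction ratios such as (B_memory - Treg)/(B_memory +
    Treg)) for association with immune-checkpoint-blockade response (AUC with
    Mann-Whitney significance) and survival (median-split Kaplan-Meier with
    log-rank tests). Includes pseudo-bulk construction from annotated
    single-cell counts with quality-control filtering, predictability calling
    via one-sample location tests with Benjamini-Hochberg correction, Mood
    median tests for clinical-covariate contribution, and a synthetic matched
    blood/tumor cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
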