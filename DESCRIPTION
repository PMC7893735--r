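Package: cfMethDx
Title: Cell-Free DNA Methylation Diagnostics for Suspicious Breast Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for distinguishing malignant from
    benign breast lesions using plasma cell-free DNA (cfDNA) methylation.
    Implements tissue-based calling of differentially methylated regions (DMRs),
    cfDNA fragment-length filtering and size selection, per-fragment inference
    of malignant origin from joint CpG methylation patterns, per-region
    "malignant ratio" marker profiles, a cross-validated random-forest cfMeth
    score, a ridge-combined model with imaging scores, and cutoff selection at
    a bounded false-negative rate. A bundled generator produces synthetic
    genomes, tissue methylomes with planted DMRs, plasma fragment sets with a
    known tumor fraction, and cohort tables with imaging covariates, so the
    whole pipeline is testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
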