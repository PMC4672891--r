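Package: comologit
Title: Comprehensible Sparse Logistic Risk Models with Comorbidity Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact, clinician-readable logistic risk models from
    electronic-medical-record style tables of binary diagnosis indicators and
    numeric covariates. A three-stage pipeline first screens pairwise
    interactions under a strong-hierarchy constraint using an overlapped
    group-lasso logistic regression path, then augments the selected terms
    with Boolean complement ("comorbidity") features encoding that exactly
    one of two diagnoses is present, and finally prunes the expanded design
    with lasso logistic regression tuned by 5-fold cross-validated AUC under
    both the optimal-lambda and one-standard-error rules. Includes a
    synthetic EMR data generator with planted main, product and switching
    effects, repeated hold-out evaluation with percentile intervals,
    selection-frequency stability tables, and interaction response surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
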