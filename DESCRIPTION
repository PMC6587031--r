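Package: mrtraj
Title: Sequential Multiparametric MR Radiomics for Breast Cancer Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomics analysis of multiparametric breast MRI built around
    trajectory ("sequential") statistics of texture features across DCE
    time points and DWI b-values. Provides a synthetic phantom cohort
    generator, 3D shape and texture feature extraction (first-order, GLCM,
    GLRLM, GLSZM, GLDM, NGTDM), per-subject and cohort-interactive
    trajectory statistics (Kendall tau-b, conservation, stability,
    dispersion), a two-stage feature selection with an elliptical
    p-value-by-CV-error acceptance gate followed by lasso/ridge/elastic-net
    rank fusion and Pearson correlation pruning, a Rad-score, and a
    20-classifier repeated stratified cross-validation comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    glmnet,
    MASS,
    rpart,
    class,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
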