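Package: pdsdiag
Title: Personalized Pathway Dysregulation Scores for Blood Metabolomics
    Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Transforms a samples-by-metabolites abundance matrix into a
    samples-by-pathways matrix of personalized Pathway Dysregulation
    Scores (PDS) by fitting a smoothed principal curve in each pathway's
    metabolite subspace and scoring every sample by its normalized
    arc-length projection.  Pathway features are then selected by
    correlation-based feature selection (CFS) with ten-fold
    cross-validation consensus, ranked by mutual information with the
    class, and used to train and evaluate case/control diagnostic
    classifiers (penalized logistic regression, support vector machine,
    random forest) with a full metric suite (AUC, sensitivity,
    specificity, MCC, F1).  A synthetic cohort generator with planted
    pathway-level dysregulation makes the whole pipeline testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
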