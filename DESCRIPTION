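Package: dnbpipe
Title: Dynamic Network Biomarker Analysis for Staged Proteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of staged, two-compartment proteomic expression
    matrices across an ordered disease progression: median normalisation
    and completeness filtering, normality-gated differential expression
    with fold-change bounds, fuzzy c-means clustering of per-stage trend
    profiles, dynamic network biomarker (DNB) composite-index scoring with
    tipping-stage detection and permutation significance, epithelial to
    mesenchymal transition (EMT) signature scoring, SVM recursive feature
    elimination biomarker-panel selection with cross-validated AUC,
    ligand-receptor crosstalk ranking between lesion and non-lesion
    compartments, and a synthetic staged-dataset generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
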