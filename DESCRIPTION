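Package: cellpheno
Title: Cellular Feature Engineering for Staging Chronic Lymphocytic
    Leukemia Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pathomics pipeline for staging chronic lymphocytic leukemia
    (CLL), its accelerated phase (aCLL), and Richter transformation (RT)
    from nuclear morphometry. Starting from per-ROI tables of segmented
    nuclei (or instance label masks), the package applies solidity and
    size quality filters, discovers three cell phenotypes by subsampled
    spectral clustering on nuclear size and intensity, propagates
    phenotype labels with multinomial logistic regression, computes three
    families of per-ROI features (unsupervised phenotype ratios and
    densities, mixed-cell morphometrics, and supervised small/large-cell
    features around an optimized size cutoff), trains gradient-boosted
    tree diagnosis models with impurity-based feature selection, and
    evaluates them with accuracy, macro-average one-vs-rest AUC, and
    repeated patient-level 1:1 splitting. A synthetic-cohort generator
    with known ground truth makes every stage testable without clinical
    slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    igraph,
    glmnet,
    xgboost,
    ranger,
    pROC,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
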