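Package: cirrus
Title: Mammographic Texture Features and Breast Cancer Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for estimating breast cancer risk gradients
    from the texture of craniocaudal-view mammograms. Segments the breast from
    the image background, applies quality control, extracts twenty gray-level
    co-occurrence matrix (GLCM) texture features made resistant to digitizer
    settings by equal-mass gray-level quantization, aggregates features to one
    record per woman, fits a Bayesian lasso logistic regression by Gibbs
    sampling with Polya-Gamma data augmentation to form a linear texture risk
    score ("Cirrus" score), and evaluates risk gradients as odds ratios per
    age- and BMI-adjusted standard deviation, with closed-form interquartile
    risk ratio and AUC conversions. Includes a synthetic image and cohort
    generator so every stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
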