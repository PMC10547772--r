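Package: ramanprom
Title: Prominence-Ratio Classification of Raman Spectra of Thyroid Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for discriminating healthy or benign
    thyroid tissue from carcinoma using Raman spectra. Spectra are regridded,
    area-normalised and spline-smoothed; pooled local maxima are fitted with a
    univariate unequal-variance Gaussian mixture selected by BIC; mixture
    components define non-overlapping spectral intervals whose per-spectrum
    prominences yield reciprocal-selected prominence-ratio features. Models
    (random forest, gradient-boosted trees, support vector machine, Gaussian
    naive Bayes) are evaluated in a nested design: per-fold Boruta consensus
    feature selection, SMOTE oversampling of the minority class, leave-one-out
    prediction, replicated over SMOTE seeds. Predictions are explained with
    run-averaged Shapley values, including an exact enumeration oracle and a
    TreeSHAP implementation for random forests. A synthetic spectrum generator
    with class-dependent cytochrome and carotenoid band profiles makes the
    whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    ranger,
    randomForest,
    xgboost,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
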