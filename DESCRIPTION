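Package: specstack
Title: Stacked Ensemble Estimation of Leaf Dry Matter from Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating leaf dry matter content (percent of fresh mass)
    from full-range (350-2500 nm) leaf reflectance spectra. Provides a spectral
    index library and index-based baselines, preprocessing (artifact screening,
    standardization, optional Savitzky-Golay smoothing, PCA reduction), a
    multi-family base-learner zoo (PCR, PLSR, elastic net, random forest,
    gradient boosting, Gaussian process regression) tuned by repeated k-fold
    cross-validation with one-standard-error selection, candidate-level stacked
    ensembling with a non-negative LASSO meta-learner fitted on out-of-fold
    predictions, contiguous-band permutation importance, residual diagnostics,
    and a seeded synthetic leaf-spectra generator with a known dry-matter
    mechanism for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    e1071,
    glmnet,
    jsonlite,
    lhs,
    mixOmics,
    ranger,
    signal,
    xgboost,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
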