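Package: radrecur
Title: Radiomics and Dosimetric Analysis of Recurrence After Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recurrence patterns of nasopharyngeal
    carcinoma after intensity-modulated radiotherapy. Classifies recurrences
    as in-field, marginal or out-of-field from the dose-volume histogram of
    the recurrent tumor volume, and implements an MRI radiomics pipeline:
    ROI preprocessing (isotropic resampling, gray-level normalization,
    64-level quantization), Laplacian-of-Gaussian and undecimated wavelet
    image filters, a 1117-feature manifest (shape, first-order and five
    gray-level texture-matrix families), a reproducibility and redundancy
    driven feature-selection cascade (ICC, Pearson pruning, Kruskal-Wallis
    with Benjamini-Hochberg correction, ROC), PCA reduction and stratified
    cross-validated classification (neural network, k-nearest neighbors,
    support vector machine). A synthetic-cohort generator with controllable
    texture heterogeneity and dosimetric ground truth supports end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    nnet,
    e1071,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
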