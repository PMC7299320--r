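Package: texomri
Title: Semi-Automatic Texture Analysis of DCE-MRI Breast Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible radiomics pipeline for two-dimensional
    dynamic contrast-enhanced MRI slices: semi-automatic lesion
    segmentation on subtraction images (Otsu thresholding inside an
    operator region of interest, morphological cleanup, largest
    eight-connected component), mu +/- 3 sigma intensity
    normalization with 8-bit quantization, a 488-feature texture
    inventory (histogram, gray level co-occurrence matrix, gray level
    run-length matrix, discrete wavelet transform), normality-gated
    univariate screening, LASSO-penalized logistic feature selection,
    leave-one-out cross-validated classification (logistic regression,
    quadratic discriminant analysis, support vector machine), and ROC
    evaluation with DeLong variance estimates and paired z-tests
    between correlated AUCs. Includes a synthetic-cohort phantom
    generator with class-conditional correlated lesion texture for
    end-to-end calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    mgcv,
    glmnet,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    nortest,
    pROC,
    MASS,
    tiff
Config/testthat/edition: 3
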