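Package: busfusion
Title: Texture-Morphology Score Fusion for Benign/Malignant Breast Ultrasound Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided classification of breast ultrasound lesions as
    benign or malignant by late fusion of two feature channels. Texture
    descriptors (local binary patterns, histograms of oriented gradients,
    gray-level co-occurrence statistics) feed an RBF support vector machine;
    morphological contour descriptors (compactness, elliptic compactness,
    radial-distance spectrum statistics) feed a Gaussian naive Bayes
    classifier; per-sample malignancy scores are combined linearly with a
    tunable weight. Includes speckle-reducing anisotropic diffusion
    preprocessing, a seeded synthetic lesion-phantom generator for
    reproducible experiments, and ROC-based evaluation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    jsonlite,
    png,
    mgcv,
    e1071,
    MASS,
    class,
    rpart,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
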