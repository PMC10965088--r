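Package: mrigrade
Title: Severity Grading of Brain Images with Hybrid Texture and Shape Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for grading dementia severity from 2-D grayscale brain
    images. Implements a hybrid bank of twelve feature extractors (gray-level
    co-occurrence statistics, local binary/ternary patterns and a radial
    variant, Gabor filter responses, wavelet log-energy, statistical and
    geometrical region properties, a boundary intersection shape signature,
    box-counting fractal dimension, and PCA/ICA filter summaries), principal
    component reduction with cumulative-eigenvalue component selection, six
    classical classifiers (twoing-rule decision trees, correlation-distance
    k-nearest neighbours, linear discriminant analysis, Gaussian naive Bayes,
    linear support vector machines, and AdaBoost/Bagging/RUSBoost tree
    ensembles) with randomised hyperparameter search, a compact 20-layer
    convolutional neural network trained by stochastic gradient descent, and a
    multiclass evaluation suite (confusion matrices, per-class sensitivity and
    precision, one-vs-rest ROC curves and AUC). A seeded synthetic brain
    phantom generator provides a four-class benchmark so the full pipeline can
    be exercised without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
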