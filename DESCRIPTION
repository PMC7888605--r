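Package: visparc
Title: Functional Parcellation of Mouse Visual Cortex from Calcium Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised classification and semi-supervised parcellation of
    the six core mouse visual areas (V1, LM, AL, RL, AM, PM) from wide-field
    (per-pixel) or two-photon (per-neuron) calcium time series. Responses
    are trial-averaged and reduced with principal component analysis
    followed by linear discriminant analysis; area membership is decoded
    with four supervised classifiers (unimodal Gaussian Bayes, Gaussian
    mixture models fitted by expectation-maximization, one-against-one
    support vector machines, and a single-hidden-layer neural network); the
    cortical sheet is parcellated by a seeded semi-supervised region-growing
    algorithm built on a universal background model with maximum-a-posteriori
    mean adaptation and a modified-BIC merge score. Evaluation utilities
    cover train/test protocols, unbiased and size-biased chance levels,
    confusion matrices, intra- versus inter-area correlation analysis and
    response-duration sweeps. A synthetic-data generator produces sheets and
    unit collections with the latent structure the analysis assumes, so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    e1071,
    nnet,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
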