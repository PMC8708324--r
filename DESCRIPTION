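Package: plantlatent
Title: Explainable Plant Image Classification via Unsupervised Latent Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage explainable classification of plant versus background
    imagery. Stage one learns latent image features without labels, either with
    a Bayesian Gaussian process latent variable model (sparse variational
    inference, radial basis function kernel with automatic relevance
    determination) or with a convolutional autoencoder. Stage two selects
    features by an ARD relevance-increase rule and Spearman rank-correlation
    tests against the class label, classifies the selected features with a
    nu-support-vector machine tuned by Bayesian optimization under repeated
    cross-validation, and reports accuracy, mutual information and McNemar
    comparisons. Latent features are visualized as sampling-based saliency maps
    whose pixel-wise significance is assessed with a spatial randomization test
    against a marked homogeneous Poisson null. A synthetic plant/soil image
    generator with ground-truth masks and optional label-correlated confounds
    makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    e1071,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
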