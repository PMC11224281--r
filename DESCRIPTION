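Package: ospreycaps
Title: Capsule Networks Trained by a Modified Osprey Optimizer for
    Blood-Smear Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the osprey optimization algorithm and a modified
    variant (sinusoidal chaos map plus multiplicative Gaussian mutation) as a
    general box-constrained derivative-free minimizer, together with a small
    capsule neural network with dynamic routing whose weights and biases are
    trained by the optimizer through the margin loss. Includes the classical
    benchmark test functions used to validate the optimizer, a synthetic
    blood-smear image generator emulating blast versus lymphocyte morphology,
    the standard augmentation operators for smear images (rotation, shear,
    scale, translation, reflection), salt-and-pepper noise, Pascal-VOC
    annotation I/O, evaluation metrics including linearly weighted kappa, and
    reproducible benchmark, ablation and cross-validation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
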