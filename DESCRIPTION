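Package: mirrorglass
Title: Simulated Psychophysics and Image-Computable Classifiers for
    Mirror Versus Glass Material Perception
Version: 0.1.0
Authors@R:
    person("Mirrorglass", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully simulated pipeline for studying how
    image-computable classifiers compare to human mirror-versus-glass
    material judgments. Provides a deterministic synthetic stimulus
    generator with plantable image cues (vertical luminance gradient,
    contrast and saturation offsets on band-pass noise), simulated
    observers producing 5-point ratings, three-way judgments,
    recognizability votes and crowdsourcing sessions with catch trials;
    hand-engineered colour-histogram and steerable-pyramid texture
    features with z-scoring and PCA; logistic-regression and parametric
    convolutional-network classifiers trained with repeated two-fold
    cross-validation; the multi-round diagnostic-image-set construction
    that decorrelates perceived from true material class; a
    human-correlation hyperparameter search over network depth;
    two-stage representational similarity analysis with multidimensional
    scaling and noise ceilings; and interpretability analyses (class
    activation maps, vertical-bias profiles, noise-robustness curves and
    the image-inversion test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
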