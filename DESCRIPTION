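Package: prefcorr3d
Title: Reverse Correlation of Facial Attractiveness Preferences in a
    Generative 3D Face Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models individual facial-attractiveness preferences by reverse
    correlation in a generative 3D morphable face space. Provides a synthetic
    generative stimulus space (categorical averages plus orthonormal identity
    bases for 3D shape and multi-band L*a*b* complexion), simulation of raters
    with planted linear preferences, robust per-dimension regression of
    stimulus coefficients on ratings, vertex- and pixel-level local models
    with false-discovery-rate control, mutual-information cross-checks,
    attractive-face reconstruction and z-scoring against the stimulus
    distribution, sexual-dimorphism cosine tests with bootstrap confidence
    intervals, a PCA representation space over individual preference models
    with group/participant variance decomposition and permutation thresholds,
    and cross-validated Gamma-GLM prediction of held-out ratings against
    averageness and dimorphism predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
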