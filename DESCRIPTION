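Package: affrf
Title: Affine Gaussian Derivative Receptive Fields and Canonical
    Decomposition of 2-D Affine Image Transformations
Version: 0.1.0
Authors@R:
    person("affrf", "developers", email = "affrf@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing 2-D affine image transformations and
    affine Gaussian derivative models of visual receptive fields. Provides
    a closed-form rotation-stretch-rotation factorization of 2x2 affine
    matrices (a modified singular value decomposition with guaranteed
    rotation factors), construction of affine maps from monocular slant
    and binocular disparity-gradient viewing geometry, closed-form and
    generalized directional-derivative receptive-field kernels
    parameterized by a spatial covariance matrix, verification of affine
    covariance of smoothed (and spatio-temporal) filter responses on
    synthetic imagery, steering of directional derivatives by linear
    combination, and semigroup cascade smoothing. Includes generators for
    synthetic test stimuli (gratings, band-limited noise, impulses),
    image warping, deformation-field visualization and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
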