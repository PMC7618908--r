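Package: hemisym
Title: Left-Right Asymmetry Mapping on Spherical Cortical Surfaces
Version: 0.1.0
Authors@R: person("hemisym", "developers", role = c("aut", "cre"),
    email = "hemisym@example.org")
Description: Tools for vertex-wise mapping of structural and functional
    left-right asymmetry of paired cortical hemispheres. Provides spherical
    mesh primitives (octasphere construction with exact mirror symmetry,
    cotangent Laplacian, surface-constrained heat-kernel smoothing),
    deformation-field algebra and a lightweight sulcal-depth-driven
    spherical registration, construction of left-right symmetric
    spatiotemporal surface templates, asymmetry-index computation
    (L - R) / ((L + R) / 2), mirror-symmetrised group ICA with dual
    regression for resting-state timeseries, and vertex-wise permutation
    inference with threshold-free cluster enhancement (TFCE) and
    family-wise error control. Includes a synthetic-cohort generator with
    planted asymmetries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
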