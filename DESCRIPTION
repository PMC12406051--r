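Package: itemsl
Title: Searchlight Decoding of Trial-Wise fMRI Responses with Inverse
    Transformed Encoding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-wise multivariate decoding for rapid event-related fMRI in
    the presence of trial-by-trial correlations induced by overlapping
    hemodynamic responses. Builds HRF-convolved trial-wise design matrices from
    BIDS-style event tables, estimates single-trial response amplitudes by
    joint weighted least squares (LS-A), separate per-trial models (LS-S) or a
    fractional ridge regression baseline, and decodes experimental design
    variables by cross-validated inversion of the multivariate transformed
    encoding model, whose trial-level covariance (the "uncorrelation matrix")
    is derived analytically from the design and calibrated by restricted
    maximum likelihood. Includes a spherical searchlight engine producing
    voxel-wise decoding-performance maps, NIfTI input/output, a rapid
    event-related design simulator, and method-comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    MASS,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
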