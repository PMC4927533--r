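Package: fiveew
Title: Five-Energy-Window Scatter and Crosstalk Correction for
    Dual-Isotope SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative simultaneous Tc-99m and I-123
    single-photon emission computed tomography (SPECT) with pixelated
    solid-state (CdTe-like) detectors.  Implements the five-energy-window
    (FiveEW) scatter and crosstalk correction, built from a
    detector-response-corrected triple-energy-window estimator (TEWDR)
    that compensates for photopeak spillover into the scatter
    sub-windows, together with a Hecht-equation detector energy-response
    model, a seeded single-scatter Monte Carlo simulator for planar and
    rotating acquisitions of calibration phantoms, OSEM tomographic
    reconstruction with uniform attenuation correction and
    distance-dependent collimator response, and phantom quantification
    metrics (cross-calibration, percentage difference, residual
    scatter).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
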