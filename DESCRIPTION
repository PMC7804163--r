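Package: drspectra
Title: Diffuse Reflectance Spectroscopy Pipeline for Tissue Classification
Version: 0.1.0
Authors@R:
    person("DRS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing fiber-probe diffuse reflectance spectra of
    soft tissue. Provides raw-spectrum calibration against reference and
    background channels, stitching of visible and near-infrared spectrometer
    channels across their overlap, min-max feature scaling, kernel support
    vector machine classification evaluated by repeated twofold
    cross-validation, and Monte Carlo photon transport in a semi-infinite
    turbid medium for photon-hitting-density probed-depth estimation at a
    given source-detector distance. A synthetic chromophore-based spectra
    generator emulates two-class (normal mucosa versus tumor) datasets so the
    full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
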