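Package: slopespec
Title: Multi-Pathlength Slope Spectroscopy for Hemoglobin in Blood Bags
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nondestructive quantification of hemoglobin in flexible blood
    bags from visible-near-infrared transmission spectra measured at
    several optical pathlengths. Provides a layered Monte Carlo photon
    transport simulator (MCML-style, with correlated absorption sweeps),
    extraction of per-wavelength slope spectra from log intensity versus
    pathlength, the difference-coefficient curve statistic, partial least
    squares regression calibration with the usual chemometric figures of
    merit, and a modified Beer-Lambert synthetic-data generator for
    benchmarking packaging-robust calibrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
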