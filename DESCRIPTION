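Package: modmap
Title: Modular Spontaneous Activity Analysis for Wide-Field Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity in wide-field calcium
    imaging movies of developing cortex: rigid registration, median-filter
    baseline and dF/F computation, detection of large spontaneous events by
    pixel-wise thresholds plus spatial criteria, Gaussian band-pass filtering
    of event frames, per-event wavelength, modularity and module-amplitude
    metrics with a bootstrap significance test, seed-point correlation fields
    with rotation/reflection surrogate null ensembles, long-range correlation
    strength, and cross-validated dimensionality (participation ratio). A
    synthetic-movie generator with known ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
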