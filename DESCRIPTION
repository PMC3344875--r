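Package: arealmap
Title: Areal Boundary Mapping from Resting-State Time Series on Cortical Flat Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates boundaries between functional cortical areas on 2D
    flat-map grids of resting-state time series. Implements a local-timecourse
    boundary mapping method (seed-wise correlation maps restricted to the
    region of interest) alongside the standard target-correlation plus eta
    squared method, both feeding a shared Canny edge detection and
    probabilistic boundary map pipeline. Includes temporal band-pass filtering
    and nuisance regression, a boundary signal-to-noise statistic with
    ridge-based Boundary/Background pixel classification, boundary-map
    similarity testing with spatial-autocorrelation-corrected degrees of
    freedom, and a synthetic flat-map generator with planted parcellations for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    RNifti,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
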