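Package: gaitcx
Title: Gait Complexity Analysis from Smartphone Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating linear and nonlinear stride-time
    variability from pocket-worn smartphone accelerometer recordings of
    free-living walking. Implements heel-contact event detection from the
    vertical acceleration signal via a continuous-wavelet-transform
    procedure, walking-bout segmentation with steady-state trimming, and
    a suite of stride-time variability measures: mean stride time,
    standard deviation and coefficient of variation, detrended
    fluctuation analysis (fractal scaling index), approximate and sample
    entropy, multiscale entropy with a complexity index, statistical
    persistence decay, and entropic half-life. A synthetic-data module
    generates fractional-Gaussian-noise stride-time series (exact
    circulant-embedding construction) and gait-like acceleration
    recordings with known heel-contact ground truth, so that every stage
    of the pipeline can be validated without access to participant
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
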