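Package: dyadsync
Title: Dyadic Head-Movement Synchrony from Accelerometry via
    Cross-Recurrence and Growth-Curve Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for interpersonal head-movement synchrony in
    dyadic conversation. Simulates dyadic 3-axis accelerometer recordings
    with controllable in-phase or turn-taking coupling, preprocesses raw
    traces (zero-phase Butterworth filtering, 10 Hz downsampling, Euclidean
    acceleration, jounce-based calibration cutoffs), computes continuous
    cross-recurrence quantification with radius calibration to a fixed
    recurrence rate and diagonal recurrence profiles over +/- 5 s, builds
    Fourier phase-randomized and sample-shuffled surrogate baselines, and
    fits growth-curve mixed-effects models of recurrence profiles with
    orthogonal lag polynomials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
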