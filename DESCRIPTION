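Package: phaselat
Title: Latency of Oscillatory Phase Effects on Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical machinery for measuring phase differences between
    trial groups in electrophysiological signals (intertrial phase clustering,
    phase opposition sum, permutation surrogates), a simulation framework
    showing how target-evoked potentials temporally distort measured
    phase-perception effects under window-based time-frequency analysis, and a
    white-noise reconstruction paradigm (impulse-response estimation by
    cross-correlation, reconstruction by convolution) that recovers the true
    latency at which oscillatory phase modulates detection. Includes
    synthetic-data generators for both the latency-distortion study and a
    full synthetic observer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
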