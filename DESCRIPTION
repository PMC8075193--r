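Package: laminarASL
Title: Laminar Perfusion fMRI Analysis with Arterial Spin Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sub-millimetre laminar arterial spin
    labelling (ASL) fMRI. Generates synthetic interleaved label/control ASL
    time-series with known laminar ground truth, separates BOLD and
    perfusion-weighted components by surround averaging and surround
    subtraction, fits the three-regressor perfusion GLM, constructs
    equi-volume cortical depth sampling, derives laminar profiles of percent
    BOLD change and absolute/relative perfusion change, and forward-simulates
    the laminar BOLD profile from perfusion profiles with a steady-state
    venous-drainage model. Also reproduces the acquisition-side partial-Fourier
    point-spread-function computations (zero-fill and POCS reconstruction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
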