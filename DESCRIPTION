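Package: owfb
Title: Spectral-Localization-Optimal Orthogonal Wavelet Filter Banks for ECG
    Hypertension Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs two-channel orthogonal wavelet filter banks that minimize
    the mean squared spectral localization (frequency spread) of the low-pass
    filter, by solving a semidefinite program over the half-band product filter
    with Kalman-Yakubovich-Popov nonnegativity constraints, followed by
    minimum-phase spectral factorization. Provides the downstream ECG screening
    pipeline built on the designed banks: WFDB-style record ingest, five-minute
    epoch segmentation with Z-score normalization, five-level periodized
    sub-band decomposition, log-energy and signal-fractal-dimension features,
    Student's t-test feature ranking, and a linear hypertension diagnosis index
    with configurable decision ranges. Includes a deterministic synthetic ECG
    generator so the whole pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
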