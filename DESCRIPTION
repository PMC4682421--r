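Package: rdisc
Title: Condensing Single-Cell Raman Spectra into Discrete Representative Peaks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control and discretization of single-cell Raman spectra.
    A continuous spectrum of more than a thousand Raman shifts is denoised by
    discrete wavelet shrinkage, baseline-corrected by piecewise fitting between
    automatically detected troughs, min-max normalized, and condensed into a
    short list of representative peaks (position, intensity, curvature) via a
    sliding local-maximum window, a curvature sharpness gate, and a
    noise-window intensity gate. Includes discrete-spectrum similarity measures
    (peak-position Jaccard, matched-intensity Pearson correlation, and their
    combination), k-nearest-neighbour and regularized linear discriminant
    classification over full and discretized representations with a repeated
    stratified split protocol, a seeded synthetic-spectrum simulator with
    ground truth, plain-text readers and writers for full spectra and the
    rDisc v1 discrete-spectrum format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
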