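Package: pcgdx
Title: Phonocardiogram Simulation, Segmentation, and Heart Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for smartphone-style digital auscultation research: a
    seeded synthetic phonocardiogram simulator covering normal sounds, third
    and fourth heart sounds, and systolic and diastolic murmurs; band-pass
    and spectral-subtraction denoising of heart sound recordings; ECG-free
    detection of the first and second heart sounds via a Shannon-energy
    envelogram; per-cycle 40x40 log-spectrogram features; a small
    convolutional neural network classifier trained with softmax
    cross-entropy and Adam; and diagnostic-accuracy statistics (sensitivity,
    specificity, predictive values) with exact Clopper-Pearson binomial
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
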