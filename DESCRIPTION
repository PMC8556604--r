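Package: icaclean
Title: Classification and Lossless Removal of Artifact ICA Components from
    Infant EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic classification of independent components of
    infant EEG as neural or artifact. Implements a robust preprocessing
    pipeline (FIR filtering, line-noise removal, robust average referencing,
    bad-channel detection, spherical-spline interpolation, gross-epoch
    rejection, ICA), six time-frequency and topographic component features
    with infant-specific spectral settings (6-9 Hz alpha), a trainable
    regularised linear discriminant classifier, lossless component removal,
    an ERP validation workflow with adaptive-mean peak amplitudes, and a
    seeded generator of labelled synthetic components and recordings for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
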