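Package: pcgmdc
Title: Heart-Sound Segmentation, Spectral Features and Mahalanobis-Distance
    Diagnosis of Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for diagnosing phonocardiogram (PCG)
    recordings. Stage one segments each cardiac cycle into the first and
    second complex sounds (CS1, CS2) using a Viola-integral envelope and
    the signed zero crossings of a short-time modified Hilbert transform
    (STMHT). Stage two extracts an eight-dimensional frequency-feature
    vector (threshold-crossing widths and spectral gravity centers of a
    smoothed secondary spectrum envelope) per cycle and reduces it to
    three principal components. Stage three classifies the reduced
    features with a seven-component Gaussian mixture whose per-class
    decision regions are chi-square(3) confidence ellipsoids on the
    squared Mahalanobis distance, adjustable through per-class confidence
    levels. Includes a synthetic PCG simulator for reproducible testing
    and the published model constants for scoring new recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
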