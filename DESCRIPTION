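Package: qrsbench
Title: Multidimensional Benchmarking of QRS Detection Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating ECG R-peak (QRS) detectors along three
    dimensions at once: detection temporal tolerance (DTT), immunity to
    muscular noise mixed at controlled signal-to-noise ratios, and QRS
    morphology. Implements four reference detectors (a
    difference/moving-average/squaring detector with an exponentially
    decaying threshold, a dual moving-average high-pass detector, a
    level-crossing ADC event-based detector, and a Pan-Tompkins style
    detector), a first-difference power SNR mixing procedure, tolerance-aware
    one-to-one beat matching, morphology-stratified TP/TB scoring, and a
    synthetic ECG/noise generator with exact ground truth so the whole
    pipeline is testable without external data. Reads and writes WFDB-style
    records (formats 212 and 16) and MIT-format beat annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
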