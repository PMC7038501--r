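Package: lobdetect
Title: Loss-of-Balance Detection from Joint EEG and EMG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of loss-of-balance (near-fall) events from
    synchronized multichannel electroencephalography (EEG) and lower-limb
    electromyography (EMG). EMG streams are binarized into ON/OFF activation
    patterns with a moving power threshold; gastrocnemius activations act as
    master triggers around which a muscular activity pattern is scored against
    learned per-leg occurrence weights, while the pre-trigger EEG is reduced to
    per-band power-trend slopes via a sliding FFT and ordinary least squares.
    An adaptive-threshold three-level logic network fuses the muscular and
    cortical evidence into a per-contraction decision. The package also ships a
    seeded synthetic generator for gait-locked EEG/EMG sessions with annotated
    slip and activities-of-daily-life events, plus an evaluation harness
    computing sensitivity, specificity and detection-time statistics.
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
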