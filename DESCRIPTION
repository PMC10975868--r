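Package: rowemg
Title: Cycle Segmentation and Performance Metrics from Surface EMG of
    Indoor Rowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Processes two-muscle surface electromyography (sEMG)
    recordings of cyclic exercise on an indoor rowing machine. Extracts a
    smoothed RMS activation envelope, automatically detects the exercise
    window, splits it into stroke cycles at prominence-filtered envelope
    minima, and computes per-individual performance parameters: training
    time, cycle count, cycle-time mean and standard deviation, rhythm-drift
    regression slope, per-cycle muscle energy, a polynomial-trend fatigue
    point, per-cycle activation peaks, and quadriceps-before-biceps
    activation-order checks. Groups of individuals are compared with a
    pooled-variance unpaired t-test computable from raw metrics or from
    printed summary statistics. A seeded synthetic-signal generator with
    full ground truth makes the whole pipeline testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
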