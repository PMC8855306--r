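Package: panicprofiler
Title: Ensemble Profiling of Real-World Panic Attacks from Sparse
    Smartphone Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the physiological profile of
    real-world panic attacks recorded with smartphone apps that sample
    heart rate (via photoplethysmography) and subjective anxiety ratings
    sparsely and irregularly during an attack. Provides a calibrated
    synthetic cohort generator for ecological-momentary-assessment style
    recordings, quality-control filtering (minimum sample count and
    clear-peak criteria), peak-relative time standardisation with linear
    interpolation onto a uniform grid, zero-phase Butterworth smoothing,
    partial-coverage ensemble averaging, and cohort-level summary
    statistics (peak heart rate, recovery time, arousal cycle counts,
    recording duration, pooled anxiety recovery slope, lifestyle and
    trigger frequencies, and survey-style percentage summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
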