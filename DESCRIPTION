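Package: weanwave
Title: Cardiorespiratory Variability Analysis for Ventilator Weaning Outcome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for analysing respiratory-pattern and heart-rate variability
    of patients undergoing weaning from mechanical ventilation. Extracts
    breath-by-breath and beat-by-beat time series from respiratory flow signals
    and R-peak event times, computes spectral descriptors of the resampled
    variability series and multilevel discrete-wavelet-transform coefficient
    statistics, ranks wavelet feature blocks with a Mann-Whitney-based Q index,
    and evaluates linear-discriminant and regularised neural-network classifiers
    with wrapper feature selection under a repeated cross-validation protocol.
    Includes a synthetic cohort generator that emulates group-dependent
    variability structure so the full pipeline can be exercised and tested
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
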