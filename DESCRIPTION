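Package: cyclecast
Title: Seizure Risk Forecasting from Multiday Cycles of Heart Rate and
    Event Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects multiday (multidien) cycles in wearable heart-rate
    recordings and self-reported seizure diaries, builds phase-conditioned
    seizure likelihood models, projects cycles and risk up to 60 days
    ahead, and evaluates forecasts pseudo-prospectively with
    time-in-warning ROC analysis, Brier skill scores and surrogate
    significance tests. Heart-rate cycles are found with a continuous
    Morlet wavelet transform and a time-averaged red-noise significance
    test, then extracted with zero-phase Butterworth bandpass filters and
    phased via the Hilbert transform; diary cycles are found by
    phase-locking (synchronization index) against fixed sinusoids.
    Includes a synthetic-data generator with planted cycles and von
    Mises phase-locked events so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
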