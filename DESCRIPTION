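Package: thermoripple
Title: Detection and Thermal Analysis of Hippocampal Sharp-Wave Ripples and
    Interictal Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Offline analysis of hippocampal local field potential (LFP)
    recordings made during controlled elevation of core body temperature.
    Detects sharp-wave ripple (SPW-R) complexes by Hilbert-envelope z-score
    thresholding with cycle-interval validation, classifies interictal
    epileptiform discharges and myoclonic events using EMG power ratios,
    locates generalized tonic-clonic seizure onset, and aggregates event
    rates and ripple features in temperature bins normalized by dwell time.
    Includes a seeded synthetic-session generator with ground-truth event
    ledgers so every stage of the pipeline can be validated without animal
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
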