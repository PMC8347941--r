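Package: gaitpress
Title: Gait Analysis from In-Shoe Plantar Pressure Sensor Pulse Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing human gait from six-channel in-shoe
    piezoresistive pressure sensors (three per foot). Simulates voltage
    recordings through a voltage-divider readout model for normal and
    abnormal gait modes, detects loading pulses, extracts load amplitudes,
    stance durations, stepping abruptness and stepping unevenness, applies
    small-sample Student-t measurement statistics, classifies the gait mode
    from per-foot load signatures, and flags rhythm and asymmetry anomalies
    associated with fall risk. Includes a reproducible simulate-extract-
    summarise-detect pipeline with CSV and JSON artifacts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
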