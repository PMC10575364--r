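Package: ppgkit
Title: Synthetic Photoplethysmography, Dense Signal-Quality Assessment and
    Device-Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hardware-free toolkit for photoplethysmography (PPG) research:
    a seeded PPG simulator with controllable heart rate, pulse-rate
    variability and motion/baseline/clipping/flatline artifacts carrying
    ground-truth quality labels at 0.5 s resolution; a band-pass and
    windowing front end; beat detection with windowed heart-rate and pNN50
    extraction; the relative power signal quality index (pSQI) and a dense
    1D convolutional encoder-decoder quality model mapping 8 s segments to
    0.5 s quality scores; device-agreement statistics (RMSE, MAE, error SD,
    Pearson r, Bland-Altman limits, exact Wilcoxon signed-rank); and a
    session CSV format with configuration files, real-time sliding-window
    metric streaming, biofeedback mapping and a multi-node start-trigger
    synchronization protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
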