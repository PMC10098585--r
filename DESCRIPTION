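Package: romahr
Title: Heart Rate and Motion-Artifact-Aware Signal Quality from Raw
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extracts heart rate from raw single-channel
    photoplethysmography (PPG) waveforms in both the time domain
    (systolic peak detection, outlier-robust 40-beat smoothing) and the
    frequency domain (short-time Fourier spectrogram peak tracking), and
    scores continuous signal quality with two indices that predict heart
    rate accuracy against an ECG reference: self-consistency (agreement
    between the two domains) and the standard deviation of the spectral
    line width. Includes readers for CSV and PhysioNet-style waveform
    records, a synthetic PPG generator with ground-truth heart rate and
    controllable motion artifacts, ROC-based cut-point discovery, and
    agreement statistics (RMSE, MAE, accuracy within 5 BPM, point-biserial
    correlation, Cohen's kappa).
License: MIT
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
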