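Package: abpmorph
Title: Arterial Blood Pressure Pulse Morphology Estimation from
    Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms raw fingertip photoplethysmogram (PPG) recordings,
    optionally combined with age and gender, into the averaged arterial
    blood pressure (ABP) pulse morphology: per-time-step pressure values in
    mmHg plus cardiac-cycle class labels (onset-to-systolic-peak,
    peak-to-dicrotic-notch, notch-to-end, ended). Includes a synthetic
    paired-waveform generator with beat-level ground truth, the full
    signal-quality pipeline (flatline and saturation screens, band-pass
    filtering, pulse delineation, per-pulse acceptance rules), onset
    -synchronized ensemble averaging with sigma-band point rejection, a
    dense-connected bidirectional GRU encoder / GRU decoder with Luong
    general attention trained under a masked multitask objective, and a
    clinical evaluation suite (marker errors, British Hypertension Society
    grading, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
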