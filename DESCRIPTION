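Package: lungphase
Title: Breathing-Phase Detection and Agreement Analysis for Lung-Sound
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting lung-sound recordings into inspiration and
    expiration phases and for quantifying agreement between phase annotations.
    Provides cropped log-magnitude spectrogram images of auscultation audio,
    Praat TextGrid and CSV annotation input/output, a baseline band-energy
    phase detector, post-processing of scored detections (confidence pruning,
    duplicate suppression, equal-amount overlap shrinking), box-level
    percentage agreement via the Jaccard index, continuous-time
    sensitivity/specificity and a pseudo-kappa statistic with shuffled-file
    chance agreement and bootstrap percentile confidence intervals, and a
    synthetic lung-sound and annotator simulator for end-to-end validation.
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
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
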