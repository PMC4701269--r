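Package: voicemark
Title: Speech Prosody Tracking and Mood-State Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for longitudinal speech biomarkers of mood.
    Estimates the fundamental frequency (F0) and pitch strength of speech by
    sawtooth-spectrum matching on an ERB-spaced auditory grid, detects voiced
    segments by pitch-strength thresholding or by short-time intensity and
    zero-crossing rate, computes per-segment prosodic features (mean F0, F0
    standard deviation, local jitter) and robust cross-segment summaries
    (median, MAD, skewness), evaluates agreement between two analysis chains
    (frame-level sensitivity/specificity, feature correlation on overlapping
    segment portions, two-sample Kolmogorov-Smirnov tests), and correlates
    session summaries with clinician-rated mood states on an ordinal
    hypomania-euthymia-depression scale via Spearman rank correlation.
    Includes a fully seeded synthetic running-speech generator with exact
    ground truth, text-file track and segment formats sized for low-bandwidth
    upload, and a command-line interface over the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
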