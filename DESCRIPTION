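Package: ambuvalid
Title: Validation of Ambulatory Wearable Heart-Rate Monitors Against Holter ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for validating heart-rate output of ambulatory
    wearable devices (wrist photoplethysmography bands, ECG shirts) against a
    criterion Holter ECG in free-living recordings. Covers conversion of R-R
    intervals to a 16-beat moving-average heart rate, cross-correlation clock
    synchronization between devices, interpolation onto criterion timestamps,
    explicit classification of underdetected versus erroneous missing data,
    agreement statistics (within-10-percent AAMI accuracy, MAE, MAPE,
    Bland-Altman bias and limits of agreement, Lin's concordance correlation
    coefficient), movement-intensity quantile stratification from triaxial
    accelerometry, normality-gated subgroup testing, and Likert comfort-score
    summaries. Includes a seeded synthetic generator of 24-hour pediatric
    cohorts with circadian heart-rate structure, activity bouts,
    motion-dependent wearable error, dropout and clock offsets, so every
    pipeline stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
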