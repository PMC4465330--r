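Package: necnirs
Title: Early Detection of Necrotizing Enterocolitis from Abdominal NIRS and
    Plasma I-FABP in a Premature Piglet Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for early detection of
    necrotizing enterocolitis (NEC) in premature piglets monitored with
    continuous abdominal near-infrared spectroscopy (NIRS) and intermittent
    plasma intestinal fatty acid-binding protein (I-FABP) sampling. Provides a
    synthetic cohort generator emulating the study design (48 h parenteral
    nutrition, 3-hourly enteral feeds to 96 h, event censoring by NEC death),
    1-minute epoching of 2-second vitals streams, per-animal baselines and
    censoring-aware group trajectories, the peri-prandial StO2 variability
    statistic around the first two feeds, a plateau-based NIRS calibration
    model against the weighted arterio-venous composite reference, empirical
    ROC construction with Youden cutoff selection for StO2 and I-FABP
    screening, biomarker trajectory summaries, Spearman correlation of jejunal
    I-FABP densitometry with histologic NEC score, and a normality-gated
    group-testing report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
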