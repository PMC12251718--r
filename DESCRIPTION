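Package: thermoglyc
Title: Skin-Temperature Variability Metrics as Digital Biomarkers of Glycemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of paired wrist skin-temperature (4 Hz)
    and continuous glucose monitoring (5-min) recordings. Aligns the
    temperature stream into backward 5-minute windows tied to each CGM
    sample, screens windows for missing data, sub-28 degree artifacts and
    mean +/- 5 SD outliers, computes current-window variability metrics
    (mean, median, SD, IQR, CV, mean amplitude deviation, a J-index
    adaptation and two M-value adaptations) and retrospective running
    metrics (mean and SD of the coefficient-of-variation series, SD of the
    window-mean series), stratifies windows by glycemic range (in / above /
    below the 70-140 mg/dL tight range) and day/night period, and compares
    ranges per subject (Wilcoxon rank-sum with Benjamini-Hochberg FDR) and
    across the cohort (linear mixed-effects models with a per-subject
    random intercept). Includes a seeded synthetic-cohort generator that
    emulates the structure of free-living recordings, with ground-truth
    labels, so the whole pipeline is testable without any real deposit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nortest,
    lme4,
    lmerTest,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
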