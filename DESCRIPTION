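Package: hemostab
Title: Automated Classification of Postinduction Hemodynamic Instability
    from Beat-to-Beat Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect clinically relevant hemodynamic instability
    after anesthesia induction from continuous noninvasive arterial blood
    pressure. Implements beat-level artifact rejection and missing-data
    exclusion rules, 1-Hz resampling with 45-s moving-average smoothing, a
    98-feature induction-window representation of systolic/mean/diastolic
    pressure and their rates of decline, expert-panel consensus labelling
    with two-way ANOVA intraclass correlation reliability statistics, and
    an imbalance-corrected classifier harness (min-max scaling, SMOTE
    oversampling, grid search toward AUROC, random-forest default) with
    threshold-based postinduction-hypotension comparators. A synthetic
    induction-waveform simulator generates labelled cohorts so the whole
    pipeline can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    knitr
Config/testthat/edition: 3
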