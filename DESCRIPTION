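Package: ctgkit
Title: Cardiotocography Signal Processing, Pattern Detection and Perinatal
    Outcome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing electronic fetal monitoring (EFM)
    tracings: a segmented-signal container for gappy 4 Hz recordings,
    ingestion of tall per-sample tracing files, sensor combination with
    precedence rules, gap repair of the fetal heart rate, rule-based
    detection of baselines, accelerations, decelerations and uterine
    contractions, epoch-wise sequential and heart-rate-variability
    feature batteries (phase-rectified signal averaging, Lomb-Scargle
    band powers, entropies, fractal measures, classical variability
    indices), an objective eight-way perinatal outcome classifier, a
    ground-truth synthetic tracing and cohort simulator, and a
    CSV-backed relational catalog of processing results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
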