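Package: delaycode
Title: Behavioral and Population Analyses for a Two-Task Visual Working-Memory Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for a mouse visual working-memory study in which
    animals alternate between a delayed non-match-to-sample (WM) task and a
    memory-independent Discrimination task with matched delay, stimulus and
    reward statistics. Provides a synthetic generator for task sequences,
    behavioral responses, neural populations and axonal boutons; psychometrics
    (delay-dependent false alarms, d-prime by delay quartile, reaction-time
    peaks, Fisher tests of optogenetic silencing effects); pooled pseudo-
    population PCA with trial-shuffled trajectory-distance nulls; regularized
    linear-discriminant coding dimensions with leave-one-out decoding,
    embedding-dimensionality sweeps and single-trial persistence statistics;
    ICA plus Gaussian-mixture clustering of axonal boutons into putative axons;
    and bootstrap quantification of optogenetic silencing effects on feedback
    activity and behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mclust,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
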