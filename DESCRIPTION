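Package: sttkit
Title: Analysis Toolkit for the Simple Tracing Test of Hand Dexterity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the simple tracing test (STT), a pen-tablet assessment
    of hand dexterity in which a subject traces a printed sine wave. From
    digitized pen traces the package computes the four STT variables (tracing
    accuracy, summed pen-pressure change, maximum pen-pressure change, and
    tracing duration), scores them with a trainable 4-3-2 multilayer
    perceptron whose published reference weights are bundled, and evaluates
    diagnostic performance with empirical ROC curves, the squared
    distance-to-corner cutoff rule, DeLong and bootstrap confidence intervals
    for the AUC, intra-class correlation reliability over one-cycle segments,
    Spearman rank correlation, and two-sample t-tests. A seeded simulator of
    healthy and motor-impaired pen traces makes the whole pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
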