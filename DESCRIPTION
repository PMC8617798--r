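Package: erpdecode
Title: Hierarchical Segment-Wise Decoding of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for decoding group membership (here, gender) from
    event-related potentials recorded in a visual oddball attention task.
    Continuous multichannel EEG is band-pass filtered, corrected for ocular
    blinks by principal component analysis, epoched around stimulus onsets,
    cleaned by amplitude-threshold artifact rejection, baseline-corrected
    and detrended, and averaged into target minus standard difference
    waveforms. The difference waveforms are partitioned into 50-ms time
    segments; each segment's per-timepoint channel vectors are classified
    with standard classifiers (3-NN, Gaussian naive Bayes, random forest,
    polynomial SVM) and aggregated by majority vote into a per-segment
    decision. Leave-one-out cross-validation across persons scores every
    segment, and the best-scoring time window is selected as the decision
    window. Includes a synthetic cohort simulator generating raw oddball
    EEG with controllable gender effects for calibration and parameter
    recovery, and Wilcoxon signed-rank tests of accuracy against chance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    class,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
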