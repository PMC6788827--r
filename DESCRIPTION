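Package: seekEEG
Title: Synthetic EEG and Time-Resolved Decoding of Confidence-Driven
    Information Seeking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the neural link between decision confidence
    and information seeking with scalp EEG. Provides a forward simulator for
    a color-mean discrimination task with free/no-choice evidence sampling
    (balanced factorial designs, constrained stimulus generation, an
    evidence-based observer with confidence-driven sampling, an inverse
    efficiency staircase, and confidence-coupled P3/Pe components embedded
    in spatially correlated noise), epoch preprocessing (baseline
    correction, event realignment across clocks, extreme-value rejection,
    per-block confidence standardization, median splits), univariate ERP
    statistics (condition averages, within-subject 1D cluster-based
    permutation tests, time-resolved single-trial regression), and the full
    multivariate decoding chain: sliding-window linear-derivation logistic
    spatial filters, Az scoring, within- and across-condition temporal
    generalization matrices with repeated stratified cross-validation and
    class balancing, shuffled-label null matrices, 2D cluster-based
    permutation inference, difficulty residualization, and peak-cluster
    comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
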