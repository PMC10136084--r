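Package: sfconn
Title: Skewness-Based Functional Connectivity for High-Frequency Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds functional networks from the high-frequency band
    (80-500 Hz) of multichannel intracranial EEG by correlating per-epoch
    envelope-skewness time series across channels (skewness-based functional
    connectivity, SFC). Provides the full analysis chain: bad-channel
    removal, bipolar rereferencing, zero-phase FIR band filtering and
    Butterworth power-line notching, upper-envelope extraction by spline
    interpolation over local maxima, one-second epoching, per-epoch sample
    skewness, Spearman rank-correlation adjacency matrices, node
    connectivity strength, pooled and patient-specific ROC/AUC localization
    of epileptic channels, bootstrap confidence intervals, and surgical
    outcome classification. A synthetic iEEG cohort generator with known
    epileptic-channel ground truth makes the whole pipeline testable
    without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
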