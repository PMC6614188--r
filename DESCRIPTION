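Package: txanomaly
Title: One-Class Anomaly Detection for Tissue Transcriptomes by PCA
    Residual Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a "tissue detector" on healthy bulk expression profiles
    only: genes are z-score standardized, a principal-component subspace is
    fitted to the healthy samples, and new samples are scored by the squared
    norm of their residual (the Q or squared-prediction-error statistic).
    Samples whose score exceeds a control limit calibrated to a stipulated
    false-alarm rate -- the Jackson-Mudholkar closed form or an empirical
    training quantile -- are called anomalous, so tumors can be flagged
    without any cancer example in training.  Includes confusion-matrix and
    rank-based AUC evaluation, a training-set-size subsampling experiment,
    and a seeded low-rank synthetic expression generator with off-subspace
    and within-subspace anomaly modes and batch-shift stress inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
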