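Package: sensorfuse
Title: Multi-Sensor Spectral Fusion for Predicting Microbial Spoilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial total viable counts (TVC, log CFU/g) in meat
    from FTIR spectroscopy, multispectral imaging (MSI) and fluorescent
    multispectral imaging (MSIF) feature tables. Implements spectral
    preprocessing (standard normal variate, Savitzky-Golay smoothing,
    fingerprint-region restriction), single-response partial least squares
    regression (NIPALS), early, mid (feature-level) and late (decision-level,
    out-of-fold stacked generalisation) multi-sensor fusion, batch-on-batch
    and repeated nested cross-validation evaluation with seed-matched folds,
    and paired Wilcoxon signed-rank model comparison with Holm-Bonferroni
    correction. Includes a synthetic multi-sensor spoilage data generator so
    the whole pipeline is testable without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
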