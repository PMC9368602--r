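Package: dxrank
Title: Multi-Label Disease Prediction over Binary-Weighted Knowledge Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts multi-label disease sets from clinical findings using an
    edge-weighted NodeRank (PageRank variant) over a bipartite disease-finding
    knowledge network with category-dependent edge weights. Includes
    negation-aware dictionary extraction of finding mentions from record text,
    an optional linear-chain CRF decoding backend for externally supplied score
    matrices, per-patient subnetwork construction with a calibration
    ("standard disease"/"gold standard") threshold pair, the five standard
    multi-label evaluation metrics (Hamming loss, one-error, ranking loss,
    average precision, micro-F1) with k-fold cross-validation bookkeeping, and
    a synthetic electronic-health-record corpus generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
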