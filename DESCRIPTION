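Package: meadrug
Title: Machine-Learning Analysis of Drug Effects on MEA Neuronal Network Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for detecting and characterizing
    drug-induced changes in neuronal network activity recorded on
    microelectrode-array (MEA) biosensors. Spike-time tables are segmented
    into sliding windows, binned into binary occupancy matrices, and turned
    into functional-connectivity graphs by pairwise correlation and
    thresholding. From each graph a panel of complex-network measures and
    community-based average-path-length scalars is extracted, together with
    the Spike-Contrast multivariate synchrony index. Pre/post-drug windows
    are classified with grouped leave-one-chip-out cross-validation across
    seven model families, scored by the bootstrap lower-confidence-bound
    AUC, interpreted with Shapley-value feature attributions, and validated
    per feature with linear mixed models that absorb chip-level repeated
    measures. A paired spike-train simulator with controllable synchrony
    makes the whole pipeline testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    lme4,
    Matrix,
    methods,
    nnet,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
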