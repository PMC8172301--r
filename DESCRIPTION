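Package: careseq
Title: Contextual Sequential Pattern Mining and Outcome Prediction from Care Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a binary in-hospital outcome from administrative care
    trajectories. Builds per-patient ordered sequences of coded hospital
    stays (ICD-10 or DRG), mines contextual maximal frequent sequential
    patterns with a PrefixSpan-style projection miner, converts trajectories
    into pattern-similarity feature vectors under nine token-level string
    measures (edit-based, q-gram and heuristic families), trains six
    classifier families over every (model, similarity, encoding)
    configuration, selects combinations by Pareto-optimal discrimination,
    and validates externally with ROC area and the Brier score. Includes a
    synthetic cohort generator with planted patterns and known ground truth.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    rpart,
    nnet,
    class,
    withr
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
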