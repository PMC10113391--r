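Package: crowdscore
Title: Scoring, Ranking and Crowd Aggregation for Microbiome
    Classification Challenges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation machinery for crowdsourced binary-classification
    challenges on microbiome profiles: scores per-sample confidence
    submissions against a gold standard with Matthews correlation
    coefficient and area under the precision-recall curve, derives
    significance thresholds from random-prediction null distributions,
    aggregates floored scores into a weighted-sum-of-ranks leaderboard,
    analyses per-sample misclassification against Shannon diversity,
    builds consensus feature signatures evaluated with a multi-classifier
    cross-validation harness, and benchmarks wisdom-of-crowd prediction
    aggregation.  A synthetic-data generator emulates a three-class
    inflammatory bowel disease cohort with group-structured taxonomy and
    pathway abundance matrices and submissions of controllable quality,
    so every stage runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    class,
    e1071,
    jsonlite,
    MASS,
    mixOmics,
    randomForest,
    testthat (>= 3.0.0),
    vegan,
    withr,
    xgboost
Config/testthat/edition: 3
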