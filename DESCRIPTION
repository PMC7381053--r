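Package: spvscreen
Title: User-Level Suicidal Ideation Screening from Social Media Posting Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a user-level suicidal-ideation
    screening pipeline for social-media post streams. A tweet-level classifier
    distills each user's timeline into a short profile version (SPV); behavioral
    (circadian sleep-time tweet ratio, weekday/weekend and quarterly posting),
    relational, tweet-statistic, lexicon-category, sentiment and image-score
    features (the SNPSY bank) are extracted per user; user-level word n-gram
    text models supply out-of-fold stacked probability features; ten
    feature-combination models are screened with Mann-Whitney U tests, fitted
    with nested cross-validation and compared with the DeLong test. A seeded
    synthetic cohort generator emulates risk, focused-control and
    generic-control user groups so the full analysis is reproducible without
    access to platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    Matrix,
    glmnet,
    randomForest,
    nnet,
    e1071,
    pROC,
    caret,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
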