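Package: crossgxe
Title: Stacked Random-Forest and Combinatorial G-by-E Interaction Modelling for Hybrid Yield Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts yield of inbred-by-tester hybrid crosses from sparse
    multi-environment trial records using a three-component stacked model: a
    random forest on one-hot genotype and environment indicators, a
    combinatorial genotype-by-environment (G-by-E) interaction-detection model
    that learns an interaction pattern matrix over {0, 0.5, 1} and the induced
    binary membership matrix by penalised local search, and a second random
    forest trained on first-stage residuals using the membership matrix as
    features. Includes a synthetic trial-data generator with planted
    interaction effects, a brute-force search oracle, nested cross-validation
    with leakage guards, parent and cluster ranking, and full cross-grid
    prediction for nominating promising biparental crosses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ranger,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
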