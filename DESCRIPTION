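Package: simspread
Title: Chemical Similarity-Guided Network-Based Inference for Drug-Target
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts biological targets for small molecules with SimSpread, a
    resource-spreading (network-based inference) algorithm on a tripartite
    drug-drug-target network whose first layer describes compounds by their
    thresholded chemical similarity to annotated drugs. Includes the bipartite
    NBI, substructure-based SDTNBI and k-nearest-neighbour baselines,
    drug-wise leave-one-out, repeated k-fold, interaction-holdout and
    time-split validation harnesses, eight ranking and binary evaluation
    metrics (AuROC, AuPRC, BEDROC, P@k, R@k, maximum MCC/F1/balanced
    accuracy), bioactivity filtering utilities, seeded synthetic fixtures with
    planted cluster-target structure, and scaffold/target diversity analysis
    of top-ranked predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    methods,
    ChemmineR,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
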