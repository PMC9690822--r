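Package: ffqrec
Title: Collaborative-Filtering Dietary Recommendations from Food-Frequency
    Questionnaire Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns participant-by-food-group daily intake tables (as derived
    from a food-frequency questionnaire) into a 1-5 rating matrix by per-group
    quintile discretization, predicts the ratings of non-consumed groups with
    user-based and item-based k-nearest-neighbour collaborative filtering
    (Pearson similarity over co-rated cells), emits health-constrained top-N
    dietary recommendation lists, and evaluates recommenders with a withheld-item
    protocol (RMSE/MSE/MAE, top-N confusion matrices, ROC and precision-recall
    curves). Includes a synthetic cohort generator with latent dietary
    archetypes so the whole pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
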