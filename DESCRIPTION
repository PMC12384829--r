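Package: pdcognet
Title: Explainable Neural-Network Prediction of Cognitive Decline in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting 3-year cognitive
    status in Parkinson's disease from baseline multimodal clinical data.
    Provides a synthetic-cohort generator with a latent-factor block
    structure and planted informative variable groups, preprocessing with
    iterative random-forest imputation and group-wise principal component
    reduction, a small feed-forward classifier trained from first
    principles with focal cross-entropy loss under stratified
    cross-validation, and a three-method explainability suite: sampled
    Shapley attributions with an exact-enumeration oracle, group-wise
    feature masking, and brute-force combinatorial masking over variable
    group subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
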