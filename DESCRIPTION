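Package: phenoval
Title: Probabilistic Validation of Claims-Code Case Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating computable phenotypes (boolean case
    definitions over diagnosis, medication and procedure claims codes)
    without exhaustive chart review. A gradient-boosted phenotype model
    trained on a rule-screened, adjudicated gold-standard cohort supplies
    per-patient case probabilities; case definitions are then evaluated
    through a probabilistic confusion matrix whose cells are cumulative
    predicted probabilities, yielding sensitivity, specificity, positive
    and negative predictive value and F-score with bootstrap confidence
    intervals. Includes a synthetic claims/EHR generator with known latent
    disease status (type 1 diabetes with a hemophilia shared-code
    confounder) so the whole pipeline can be exercised and calibrated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    xgboost,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
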