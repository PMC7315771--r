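Package: gradedCAT
Title: Polytomous Item Banking and Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and administering computerized adaptive
    tests (CAT) from polytomous item-response-theory item banks, aimed at
    mental-health screening instruments.  Implements response-category
    probabilities, likelihoods and Fisher information for the graded
    response model (GRM), the generalized partial credit model (GPCM) and
    the nominal response model (NRM); marginal-maximum-likelihood EM item
    calibration with AIC/BIC model comparison; an item-screening pipeline
    (unidimensionality check, S-X2 item fit, differential item functioning
    via ordinal logistic regression, discrimination filtering); a CAT
    engine with expected-a-posteriori scoring, maximum-Fisher-information
    item selection and standard-error stopping rules; post-hoc simulation
    studies comparing adaptive and full-bank scoring; and screening
    evaluation metrics (marginal reliability, sensitivity, specificity,
    Youden index, AUC).  Ships a calibrated 68-item separation-anxiety
    item bank as an example fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
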