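Package: metastackr
Title: Stacked Meta-Learners for Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops and evaluates stacked-generalization meta-learners that
    combine a penalized regression base-learner (ridge with restricted cubic
    splines) and a multi-layer perceptron base-learner for predicting
    continuous symptom-severity and binary dropout outcomes from routinely
    collected patient-level data. Out-of-sample base-learner predictions are
    generated by bootstrap resampling across multiply-imputed datasets,
    averaged per patient, and used as the sole inputs of unregularized
    linear/logistic and perceptron meta-learners. Includes chained-equations
    multiple imputation with spline bases and predictive-mean matching,
    bootstrap performance evaluation with percentile confidence intervals,
    calibration-in-the-large, permutation feature importance, leave-one-region
    internal-external cross-validation, and a synthetic cohort generator with
    oracle ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
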