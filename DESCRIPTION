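Package: pshscreen
Title: Conditional Feature Screening and Prognostic Modeling for Competing
    Risks under the Fine-Gray Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building prognostic models from high-dimensional
    feature data (for example, gene expression) when the survival endpoint
    is subject to competing risks. Implements proportional subdistribution
    hazards (PSH, Fine-Gray) regression via the censoring-weighted partial
    likelihood, conditional sure-independence screening that ranks features
    by their adjusted marginal contribution to the PSH partial likelihood
    (PSH-CSIS), component-wise likelihood boosting with mandatory
    unpenalized clinical covariates, inverse-probability-of-censoring
    weighted prediction-error (Brier) curves with bootstrap .632+
    correction, time-dependent ROC/AUC for predicted cumulative incidence,
    Gray's K-sample test and Aalen-Johansen estimation for risk-group
    comparison, and a Fine-Gray data simulator for validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    cmprsk,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
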