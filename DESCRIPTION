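Package: negsymprog
Title: Prognostic Modelling of Negative Symptom Outcomes in Clinical High-Risk Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic modelling of 9-month negative-symptom outcomes in
    individuals at clinical high risk (CHR) for psychosis from baseline SIPS negative-symptom
    items and regional cortical gyrification. Implements leave-site-out nested cross-validation
    of linear classifier ensembles, stacked combination of clinical and neuroimaging models,
    posterior inference on balanced accuracy via Beta posteriors on sensitivity and specificity,
    cross-validation-ratio feature importance, and two-stage sequential Bayesian risk
    stratification with number-needed-to-treat estimation. Includes a multi-site synthetic
    cohort generator so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: glmnet, e1071, jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
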