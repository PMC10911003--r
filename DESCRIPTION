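Package: fpclaims
Title: False-Positive Diagnosis Ratios in Aggregated Claims Data via the
    Illness-Death Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and sex-specific false-positive ratios (FPR) of
    chronic-disease diagnoses in aggregated health-insurance claims data.
    The prevalence of an irreversible chronic condition, its incidence
    rate, the general mortality and the mortality rate ratio of diseased
    versus non-diseased people are linked by a partial differential
    equation derived from the illness-death model.  Requiring observed
    (possibly misclassified) prevalence and incidence to be consistent
    with that equation identifies the specificity of the coded diagnoses
    for any assumed sensitivity; uncertainty about the sensitivity is
    propagated by Monte Carlo sampling.  The package fits smooth rate
    surfaces to stratified tables, inverts the equation for specificity
    by bracketed root finding, converts specificities to absolute counts
    of falsely diagnosed people, and ships a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
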