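Package: mpsipredict
Title: Phenotype-Severity Prediction for Mucopolysaccharidosis Type I
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a three-step algorithm for early prediction of
    phenotypic severity in newborns with mucopolysaccharidosis type I
    (MPS I): severe-genotype matching against a curated mutation list,
    three-zone classification of residual alpha-L-iduronidase (IDUA)
    activity in cultured fibroblasts with rule-in and rule-out cut-offs,
    and a clinical-findings tiebreak for gray-zone patients. Includes the
    exact small-sample statistics used to construct and internally validate
    the algorithm (pair-counting ROC/AUC, probability-based two-sided
    Fisher test, exact Mann-Whitney U), a packaged 30-patient reference
    cohort and 25-mutation severe list, sensitivity/specificity evaluation
    with indeterminate accounting, a seeded synthetic-cohort generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
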