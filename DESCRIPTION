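Package: ruleexplain
Title: Rule-Based Explanation of Black-Box Clinical Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Explains individual predictions of an arbitrary black-box
    classifier with a separately mined class associative classifier.
    Provides supervised minimum-description-length discretization of
    continuous features, Apriori-style mining of class association rules
    for the outcome values of interest, a three-stage pruning cascade
    (redundancy pruning, confidence-difference pruning, and a
    clinically-meaningful value whitelist), an intervention registry that
    marks rules actionable, two diversified rule-display algorithms,
    Youden-index cutoff selection with classification and
    explanation-coverage metrics, and a synthetic electronic-medical-record
    cohort generator with planted rule structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
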