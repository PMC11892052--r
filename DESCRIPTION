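Package: rxscreen
Title: Off-Label and Contraindicated Prescription Use Screening and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a drug-indication and drug-contraindication knowledge base
    from concept-pair tables with SNOMED CT to ICD-10-CM mapping, classifies
    survey-reported prescriptions against patients' recorded medical conditions
    (narrow and broad indicated use, contraindicated use, and indicated-but-not-
    contraindicated use), aggregates prevalence tables by demographic strata and
    therapeutic class, and estimates person-level associations between use
    patterns and health status or healthcare utilisation via linear probability
    models with robust standard errors, probit average marginal effects, and a
    cross-fitted double machine learning partially linear estimator. Includes a
    synthetic microdata generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sandwich,
    ranger,
    rpart,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
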