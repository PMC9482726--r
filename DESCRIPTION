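Package: riskgrader
Title: Polygenic Risk Grading and Deleterious-Variant Gene Discovery for
    Autism Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades autism spectrum disorder severity from annotated exome
    variant data along two complementary arms. The first arm is a polygenic
    risk classifier: per-variant allelic odds-ratio association ranks
    variants, a Cauchy-prior regularized logistic model turns the top-ranked
    dosages into per-sample risk probabilities, and a leave-one-out
    cross-validation loop with fold-nested feature selection evaluates the
    classifier (accuracy, sensitivity, specificity, Matthews correlation,
    ROC AUC, reclassification measures) and clusters risk scores into
    molecular subtypes. The second arm is a rule-based "important gene"
    caller that filters homozygous-alternate SIFT/PolyPhen-damaging variants,
    applies an at-least-(n-2) commonality rule within clinical sub-phenotype
    groups, partitions the resulting gene sets across groups, and validates
    them against external autism gene lists. A seeded synthetic-cohort
    generator with planted risk variants and planted damaging genes makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
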