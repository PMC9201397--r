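Package: almval
Title: Agreement and Diagnostic Validation of Paired Body-Composition
    Measurements
Version: 1.0.0
Authors@R:
    person("Paul", "Verbeek", email = "p.verbeek@posteo.net",
           role = c("aut", "cre"))
Description: Validation toolkit for comparing a candidate body-composition
    device (such as multi-frequency bio-electrical impedance analysis)
    against a reference device (dual-energy X-ray absorptiometry) on paired
    subject-level measurements of appendicular lean mass and fat-free mass.
    Computes method-comparison agreement statistics (mean bias, percent
    bias, mean absolute error, percentage of predictions within 5% of the
    reference, Bland-Altman limits of agreement, proportional-bias
    regression), derives sex-specific lowest-quintile cut-offs as a
    low-muscle-mass proxy and reports diagnostic sensitivity and
    specificity, compares misclassified against correctly classified
    subjects, and generates synthetic paired cohorts with controlled bias
    and noise so the whole pipeline can be exercised without clinical data.
    Includes a command-line interface producing a tabular validity report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
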