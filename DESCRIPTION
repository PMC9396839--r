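Package: qsarval
Title: External Validation Criteria for QSAR Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the scalar metrics and criterion families used to judge the
    external (test-set) predictivity of quantitative structure-activity
    relationship (QSAR) models from paired experimental and calculated
    activities: the Golbraikh-Tropsha rules (squared correlation, slopes of
    regressions through the origin, and the through-origin determination
    coefficients under several conventions), Roy's rm2 metric, Lin's
    concordance correlation coefficient, an independent t-test comparing
    training and test absolute errors, and the mean-absolute-error versus
    training-range GOOD/MODERATE/BAD classification. Ships a compiled
    benchmark of summary statistics for 44 published QSAR models, a
    reproduction harness for its criterion verdicts and headline counts, a
    seeded synthetic-dataset generator with controlled bias, noise and
    outlier contamination, CSV input, JSON/TSV reporting and a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
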