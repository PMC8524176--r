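Package: metasym
Title: Metacognitive Asymmetry Analysis for Signal Detection Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates signal-detection observers performing staircase-calibrated
    two-alternative discrimination with continuous confidence ratings, and
    analyses the resulting trial tables for metacognitive asymmetries:
    response-conditional type-2 ROC curves and their areas (auROC2), an
    equal-variance SDT-matched null for the asymmetry, zROC slopes, one-tailed
    t-tests with JZS (Cauchy-prior) Bayes factors, power and minimal-effect
    calculations, Bayes-factor design simulation, and prior robustness regions.
    Includes trial- and participant-level exclusion rules and an end-to-end
    experiment report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
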