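Package: corsiblocks
Title: Simulation and Analysis of the Computerized Corsi Block-Tapping Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Administers and scores a computerized Corsi block-tapping test
    (CBT) with partial-credit serial-recall scoring, simulates synthetic
    cohorts of respondents with a latent-span model (musician/non-musician
    designs with sex and age structure and metacognitive self-assessment),
    and runs the full group-comparison analysis: descriptives with Student-t
    intervals, ANCOVA with partial eta squared and assumption checks
    (Levene, covariate independence, homogeneity of regression slopes),
    correlations, Mann-Whitney and t tests, and a metacompetence
    contingency analysis. Includes a simulation harness for type-I error
    and power calibration of the inferential pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
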