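Package: phenazox
Title: Mechanistic and Kinetic Analysis of Biological Phenazine Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the biological oxidation of
    phenazine-1-carboxylic acid (PCA) by anaerobically respiring bacteria.
    Provides a mechanistic flux model of a branched anaerobic electron
    transport chain with genotype knockouts, quinone-reductase
    compatibility and pregrowth-dependent reductase expression; a
    locally-weighted-regression (LOWESS) pipeline that extracts maximum
    oxidation rates and time-to-half-oxidation from plate-reader
    fluorescence decay curves; pairwise Bonferroni-corrected comparison of
    replicate metrics; an electron-tower screen for thermodynamically
    permitted phenazine/quinone/terminal-electron-acceptor couplings; and a
    synthetic plate-reader and chronoamperometry data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
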