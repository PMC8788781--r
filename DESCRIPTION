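Package: tubulomics
Title: Phenotype-Guided Single-Tubule Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for functional proteomics of single microperfused
    kidney tubules. Derives electrophysiological phenotypes from perfused-tubule
    recordings (sealed-end cable analysis for transepithelial resistance and
    diameter, equivalent short-circuit current, amiloride-sensitive voltage, and
    paracellular Na/Cl permeability ratios from NaCl dilution potentials via the
    Goldman-Hodgkin-Katz voltage equation), quantifies targeted
    parallel-reaction-monitoring data with transition-quality filtering and
    log2 double-centering, performs untargeted differential analysis with
    downshifted missing-value imputation and iBAQ copy-number estimation, and
    integrates proteome with phenotype through correlation matrices,
    hierarchical clustering, PCA, chord-contribution statistics, and
    covariation-versus-knockout-regulation comparisons. A synthetic
    tubule-cohort simulator with full ground truth supports recovery testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
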