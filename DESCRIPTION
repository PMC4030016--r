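Package: virtumor
Title: Virtual Tumor Cell Simulation for Drug Sensitivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation of cancer cell-line "avatars" on a reduced
    signaling and cell-cycle reaction network. Genetic perturbations (mutation,
    copy-number change, knockdown) are overlaid on a control epithelial network,
    drugs are applied as dose-dependent perturbations of their target reaction
    nodes, and five phenotype indices (proliferation, survival, apoptosis,
    viability, relative growth) are scored over a three-state simulation
    protocol (control, disease, drug-treated). Includes avatar calibration
    against alignment-drug response data, dose-response/IC50 estimation,
    mutant-versus-wild-type association testing, prospective panel concordance
    statistics, and a seeded synthetic panel generator with known ground-truth
    sensitivities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
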