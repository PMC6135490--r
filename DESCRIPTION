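Package: lseifba
Title: Transcriptome-Constrained Prediction of Brain Metabolic Fluxes
    by Least-Squares Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the steady-state flux distribution of brain central
    energy metabolism in healthy tissue by flux balance analysis under
    measured exchange-rate and flux-ratio constraints, certifies its
    uniqueness by flux variability analysis, and predicts the diseased
    flux distribution from case/control gene-expression fold changes by
    least squares with equality (mass balance) and inequality
    (irreversibility) constraints (Lsei-FBA), including per-reaction
    displacement uniqueness certificates, label-permutation significance
    tests, Fisher meta-analysis across studies and Holm-Bonferroni
    family-wise error control. Ships a curated 69-reaction model of brain
    central metabolism spanning glycolysis, the pentose phosphate
    pathway, the TCA cycle, oxidative phosphorylation, redox shuttles,
    the GABA shunt and the glutamine-glutamate cycle, plus a synthetic
    expression-study generator with known flux ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
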