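Package: vialdose
Title: Reaction-Vial Dosimetry and Labelling Optimization for Bi-213 Radiopharmaceuticals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for planning Bi-213 radiolabelling reactions: closed-form
    branching Bateman decay-chain kinetics for the Bi-213/Po-213/Tl-209/Pb-209
    chain, a Monte Carlo straight-line continuous-slowing-down-approximation
    transport engine for alpha particles, beta spectra and electron lines in a
    conical reaction vial, absorbed fractions and S-values per nuclide and
    fill volume, dose-rate and cumulative-dose curves, molar energy-rate
    metrics, and radiochemistry calculators (specific activity, osmolarity,
    dilution, logistic incorporation-yield fitting, quencher requirement,
    radiochemical-purity thresholds) together with synthetic-data generators
    for incorporation and stability experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
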