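Package: hingeforge
Title: Conformational Transitions, Rigid Domains, Interfaces and Binding
    Isotherms for Two-State Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing proteins that switch between two
    conformations. Reads and writes macromolecular structures, extracts
    C-alpha traces, detects rigid domains from difference distance
    matrices, measures interdomain rotation angles and atom-pair
    distances, computes solvent-accessible surface and buried interface
    areas by Shrake-Rupley sphere sampling, and generates transition
    pathways between two conformations with an iterative dual-endpoint
    biased morphing protocol on an elastic-network backend. Also fits
    ligand-binding data: the quadratic (ligand-depletion) fluorescence
    titration model and the one-set-of-sites isothermal titration
    calorimetry isotherm, with simulators for both. A synthetic-data
    module generates hinge-motion protein pairs and noisy titration and
    calorimetry data sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
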