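Package: chaperesp
Title: Structure-Based Prediction of Pharmacological Chaperone Responsiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether missense variants of lysosomal enzymes respond
    to pharmacological chaperone treatment, from protein structure. Computes
    residue-residue contact maps and circuit-topology relations (series,
    parallel, inverse parallel, cross) including a per-residue local circuit
    topology statistic; assembles per-variant feature tables (stability change
    upon mutation, ligand proximity, contact counts, catalytic-domain
    membership, B-factors, optional PSSM profiles); applies a published
    decision-rule cascade to call variants responsive or non-responsive with
    leaf probabilities; and solves a steady-state kinetic model of folding,
    chaperone binding and export in the endoplasmic reticulum that links
    folding order to rescuability. Includes synthetic-data generators for
    structures, contact maps and labelled variant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
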