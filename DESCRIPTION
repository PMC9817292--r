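Package: smivis
Title: Coordinated Visualization of SMILES Token Attribution Scores
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Explainable-AI attribution scores computed for SMILES strings
    live on tokens, not only on atoms: brackets, ring-closure digits,
    parentheses and charges all carry scores that cannot be painted onto a
    molecule diagram directly. smivis lexes a SMILES string into typed
    tokens, binds per-atom or per-token score vectors to them, resolves
    token/substructure correspondences (atoms, rings, bracket groups,
    branches), maps scores through clamped diverging colormaps with
    threshold highlighting, and renders a coordinated molecule-heatmap plus
    token bar-chart panel to SVG and multi-molecule HTML galleries. A
    token-substitution sensitivity-score method for black-box SMILES
    predictors and per-atom Wildman-Crippen logP contributions are included
    to generate realistic attribution data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    ChemmineOB,
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'attribution.R'
    'backend.R'
    'cli.R'
    'config.R'
    'io.R'
    'layout.R'
    'render.R'
    'scores.R'
    'smivis-package.R'
    'tokenize.R'
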