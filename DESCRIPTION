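Package: znsight
Title: Template-Based Prediction of Zinc and Transition-Metal Ion Binding
    Sites in Protein Structures
Version: 0.1.0
Authors@R: person("znsight", "developers", role = c("aut", "cre"),
    email = "znsight@example.org")
Description: Predicts zinc (and, by coordination similarity, other
    transition-metal) ion binding sites in protein structures.  Candidate
    sites are found by an inverted-index search over residue-pair types and
    Calpha/Cbeta distances against a curated library of experimentally
    observed coordination templates; the ion is placed by non-linear least
    squares against ideal coordination distances; predictions are scored by
    distance deviation, template superposition RMSD and histidine imidazole
    orientation, and converted to calibrated probabilities by Platt scaling.
    Includes histidine chi2 rotamer sampling for predicted models, a
    synthetic-site generator for testing, a Metal3D-style benchmarking
    protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
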