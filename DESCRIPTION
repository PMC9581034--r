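Package: dockgat
Title: Graph-Attention Quality Assessment of Protein-Protein Docking Decoys
Version: 0.1.0
Authors@R:
    person("dockgat", "maintainers", email = "dockgat@example.org", role = c("aut", "cre"))
Description: Scores candidate protein-protein docking models (decoys) as
    near-native or incorrect with a graph attention network over residue
    contact graphs. Provides PDB structure input, CAPRI-derived quality
    labelling (fnat, interface RMSD, ligand RMSD), residue-graph
    construction with physico-chemical and sequence-profile node features,
    a two-layer graph attention classifier with interface-restricted
    top-k sort pooling, bootstrap-ensemble training for extreme class
    imbalance, enrichment-factor and success-rate ranking evaluation, and
    a rigid-body decoy simulator with analytically known quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
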