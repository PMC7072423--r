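Package: mtscreen
Title: Multi-Target Virtual-Screening Post-Processing and Prediction Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of multi-target molecular-docking screens.
    Reads ligand-by-target binding-affinity matrices (signed kcal/mol or
    unsigned magnitudes of negative affinities), extracts best-pose
    affinities from AutoDock Vina docked PDBQT files and console logs,
    computes per-compound and formulation-level prediction efficacy under
    a pass-filter threshold, assigns per-target best binders, builds the
    bipartite drug-target network of passing interactions with SIF and
    GraphML export, and generates synthetic screening matrices with
    planted per-target champions for validation. Ships the Triphala
    churna angiogenesis (15 phytochemicals x 27 VEGF-pathway targets) and
    inflammation (15 phytochemicals x COX-2/5-LOX) screens as fixtures,
    each as printed and with documented errata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
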