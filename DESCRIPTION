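Package: coreScaffold
Title: Systematic Lesion Analysis of Structural Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates single-node and single-edge lesions across cohorts of
    weighted, undirected structural brain networks and tests their effects on
    global network topology. Node removals are assessed with paired t tests on
    characteristic path length and mean local efficiency; edge removals with a
    paired Hotelling T-squared test on a four-metric global feature vector
    (assortativity, characteristic path length, density, transitivity) under
    Bonferroni correction over all G(G-1)/2 node pairs. Edges whose removal
    significantly degrades global topology form the network's core scaffold.
    Spatial structure of lesion effects is characterized by PCA of a
    lesion-effect correlation matrix and by multilinear PCA of a rank-3
    edge-effect tensor. Includes a seeded synthetic-cohort generator with
    modular topology and planted bridge edges for validation, plus TSV/JSON
    and Circos-compatible exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
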