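Package: csnpharm
Title: Chemical-Space-Network Pharmacology for Natural-Product Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A network-pharmacology toolkit built around chemical-space-network
    (CSN) clustering of compound libraries. Computes hashed circular (Morgan-type)
    fingerprints from SMILES, Dice similarity matrices, a 2-D t-SNE embedding, and
    a distance-thresholded chemical-space network whose connected components define
    compound clusters scored by mean within-group similarity (MWGS) and closeness
    centrality. Downstream stages cover score-threshold filtering of disease gene
    tables, compound-disease-DEG set intersections, Maximal Clique Centrality (MCC)
    hub ranking of protein-protein interaction networks, hypergeometric
    over-representation with Benjamini-Hochberg control, a Pearson correlation
    screen of expression data, and HOMO-LUMO gap descriptor tables. A synthetic-data
    module with planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
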