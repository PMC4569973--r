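Package: bindscape
Title: Binding Promiscuity Analysis of Structurally Resolved
    Compound-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing small-molecule binding
    events in protein crystal structures. Extracts ligand binding pockets
    from PDB/mmCIF files by heavy-atom contact geometry, collapses
    redundant pockets with Bray-Curtis complete-linkage clustering and
    homologous targets by sequence identity, classifies compounds as
    drugs or metabolites against reference libraries, and labels
    compounds promiscuous or selective by their non-redundant target
    pocket count. Provides promiscuity propensity profiles over
    physicochemical descriptor bins with standard errors, amino-acid
    composition propensities of pockets, per-compound EC-class entropy
    and pocket-variability statistics, partial least squares, support
    vector machine and classification-tree prediction models, and
    Fisher-exact pathway enrichment with Benjamini-Hochberg correction.
    A synthetic-data generator produces complete input bundles with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    ChemmineR,
    igraph,
    mixOmics,
    e1071,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
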