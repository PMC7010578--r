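Package: mddnet
Title: Pathway Cross-Talk and Interactome Subnetwork Analysis of Disease Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A three-stage systems-biology pipeline for curated disease-gene
    lists, developed around a major depressive disorder (MDD) candidate-gene
    study: hypergeometric over-representation analysis of a seed gene list
    against gene-set annotations with Benjamini-Hochberg false discovery rate
    control; construction of a pathway cross-talk network in which two gene
    sets are connected when they share a minimum number of seed genes, scored
    by the mean of the Jaccard and Overlap coefficients; and extraction of a
    disease-specific subnetwork from a protein-protein interactome by an
    approximate Steiner minimal tree, reporting the non-seed connector genes
    the tree introduces. Ships the transcribed pathway/seed fixtures of the
    motivating MDD study and a synthetic-data generator with known ground
    truth so every stage is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
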