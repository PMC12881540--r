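Package: sslrda
Title: Self-Supervised Graph Representation Learning for ncRNA-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns node embeddings from a sparse ncRNA-disease association
    network by graph self-supervised learning and predicts unobserved
    associations with an extremely randomized trees classifier. Three
    embedding engines are provided, each in a homogeneous-graph and a
    bipartite (heterogeneous) variant: a contrastive engine that matches
    graph-propagated structural features against MLP attribute features
    (triplet margin or InfoNCE objectives), a contrastive engine that matches
    local graph convolution features against global features from a learned
    hypergraph, and a generative masked-feature autoencoder. Includes a
    synthetic block-structured benchmark generator, five-fold cross-validation
    with classification (AUC, AUPR, F1) and knowledge-graph ranking metrics
    (MR, MRR, Hits@N, and per-entity local variants), and a command-line
    interface for simulation, evaluation and candidate ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    ranger,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
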