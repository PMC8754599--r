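Package: heterorx
Title: Heterogeneous Network Representation Learning for Drug-Disease
    Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles typed heterogeneous networks linking drugs, target
    proteins, diseases and Gene Ontology terms; learns structural compound
    embeddings with a self-attention sequence autoencoder over SMILES,
    functional and network embeddings with node2vec (biased second-order
    random walks plus Skip-gram with negative sampling), and global node
    embeddings with an attention-based graph neural network; and predicts
    drug-disease associations with a random-forest classifier under
    stratified cross-validation. Includes hypergeometric GO-term enrichment,
    cosine-similarity virtual screening with t-SNE projection, a seeded
    synthetic benchmark generator with planted block structure, and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
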