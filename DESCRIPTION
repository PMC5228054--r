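Package: dtnn
Title: Deep Tensor Neural Networks for Molecular Energy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Size-extensive prediction of molecular energies from nuclear
    charges and interatomic distances with a deep tensor neural network:
    learnable per-element embeddings are refined by low-rank factorized
    tensor interaction passes over Gaussian-expanded distances, and a
    two-layer head predicts per-atom energy contributions whose sum is the
    molecular energy. Includes mini-batch SGD training with momentum and
    checkpoint-best early stopping, extended-XYZ input/output (plain and
    GDB-9 comment-line dialects), seeded synthetic datasets labelled by
    analytic pairwise potentials, interpretation instruments (atomic energy
    partitioning, substructure stability ranking, local chemical potential
    grids from a probe atom with Gaussian cube export) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
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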