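Package: cellcrosstalk
Title: Cell-Cell Interaction Inference from Single-Cell RNA-Seq with Joint
    Autoencoder and Graph Convolutional Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cell-cell interactions from single-cell RNA sequencing
    data. Cells are clustered without supervision by a jointly trained
    autoencoder and graph convolutional network over a K-nearest-neighbour
    cell graph, with Student's-t soft assignments sharpened by a
    self-training target distribution. Ligand-receptor interactions between
    the resulting clusters are scored as products of truncated-mean complex
    expression (geometric means over subunits), labelled significant by a
    majority vote over three statistical scorers, and optionally re-predicted
    by a supervised residual-network plus graph-convolutional classifier over
    a ligand-receptor pair correlation graph trained with focal loss.
    Includes a deterministic synthetic-data generator with planted clusters
    and planted ligand-receptor signals, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
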