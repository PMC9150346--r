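Package: rwrt
Title: Protein Function Prediction by Bi-Random Walks with Restart on a
    Functional Similarity Tensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology Biological Process annotations for
    proteins from a protein-protein interaction network, protein domain
    content and a protein-complex catalog.  The three evidence sources are
    assembled into a sparse n x n x 3 functional-similarity tensor; a
    coupled bi-random walk with restart on the tensor scores functional
    similarity between proteins; candidate partners with low cohesiveness
    are filtered out and target proteins are annotated with the top-ranked
    functions of the surviving partners.  Includes a synthetic planted-module
    data generator and a cross-validation evaluation harness (leave-one-out,
    ten-fold, ROC/AUROC, matching statistics, single-network ablation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
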