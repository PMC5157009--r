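Package: ontonet
Title: Semi-Supervised Inference of Gene Ontology Structure from
    Heterogeneous Molecular Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns from a trusted sub-tree of an existing gene ontology how
    to filter, discretize and linearly integrate multiple heterogeneous
    weighted gene networks, infers a new ontology DAG from the integrated
    network by descending-threshold clique extraction (CliXO-style), and
    evaluates the inferred DAG against the reference ontology on held-out
    parts via gene-set alignment with an FDR cutoff. Includes a synthetic
    ontology/network generator with known ground truth so every stage of the
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, GO, NetworkInference, Annotation
RoxygenNote: 7.3.3
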