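Package: cascclust
Title: Cascaded Protein Sequence Clustering via Greedy Vertex Cover
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Representative-based clustering of protein sequence sets at
    controllable depth. Sequences are compared by local alignment and a
    clustering criterion (e-value, sequence identity, uni- or bi-directional
    coverage); accepted alignments form a directed can-represent graph from
    which clusters are extracted by a depth-bounded greedy vertex cover.
    Scaling is achieved by cascaded rounds of increasing alignment
    sensitivity, linear-stage candidate generation over shared seeds with
    minimizer subsampling, length-ratio pruning for bi-directional coverage,
    and empirically learned multiple spaced seeds. Includes a
    domain-architecture based evaluation of clustering sensitivity and
    precision, a synthetic protein-family simulator for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
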