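Package: complexpred
Title: Two-Stage Supervised Protein Complex Prediction from Weighted PPI Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts protein complexes from protein-protein interaction (PPI)
    networks with a two-stage supervised pipeline. Edges are first weighted by
    combining a high-order common-neighbor topological similarity with a Gene
    Ontology annotation-overlap similarity. Stage one (SVCC) seeds candidate
    subgraphs from maximal cliques, scores them with a polynomial-kernel
    support vector classifier over sixteen topological features, and grows and
    filters them by overlap. Stage two embeds nodes with biased random walks
    and skip-gram learning, averages member vectors into complex vectors, and
    keeps candidates a random forest classifies as genuine complexes. Includes
    neighborhood-affinity evaluation, hypergeometric GO enrichment, a
    five-fold cross-validation protocol, and a synthetic planted-complex
    benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
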