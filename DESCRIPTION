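Package: sigreverse
Title: Disease-Drug Transcriptomic Reversal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates a disease differential-expression signature with
    drug-versus-vehicle RNA-seq count data to identify genes regulated by
    drugs in the direction opposite to the disease ("transcriptomic
    reversal"). Provides CPM computation, low-expression filtering, TMM
    normalization factors, a Welch test on log2-CPM, Benjamini-Hochberg
    adjustment, multi-drug reversal intersection accounting,
    hypergeometric over-representation analysis against GMT gene-set
    collections, protein-protein-interaction subgraph clustering with a
    permutation edge-enrichment test, node annotation for network export,
    and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
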