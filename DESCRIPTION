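Package: sembic
Title: Semantic Biclustering of Binary Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Finds rectangular patterns in binary gene-expression matrices
    that can be jointly described by ontology terms annotating both the gene
    and the situation (sample) dimension.  Implements two strategies: a
    noise-tolerant greedy bicluster search followed by bi-directional
    enrichment analysis, which yields soft semantic biclusters built from
    weighted ontology terms, and a reduction to propositional rule and
    decision-tree learning over an instance-per-cell unrolling of the matrix.
    Both strategies produce classifiers of arbitrary (gene, situation) pairs
    and are evaluated with a rectangular train/test split and ROC analysis,
    including a threshold-grid convex-hull AUROC and per-region
    (seen-gene/seen-situation) generalization scores.  A seeded generator of
    random ontologies, annotations and matrices with planted semantic
    biclusters supports fully self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
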