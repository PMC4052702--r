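Package: plsdex
Title: Partial Least Squares Differential Expression with Permutation-Based FDR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis of two-group log2 expression
    matrices by partial least squares (PLS). Latent variables are extracted
    with the single-response NIPALS algorithm, probes are ranked by variable
    importance on the projection (VIP), and significance is assessed against a
    permutation-based empirical null with a pooled tail-ratio false discovery
    rate. Downstream stages include hypergeometric over-representation testing
    of selected genes against flat term annotations, and degree-based hub
    detection on a protein-protein interaction network induced by the selected
    genes. A synthetic-data generator emulating a two-group microarray design
    with planted effects, an enriched term, and planted hubs makes every stage
    testable end-to-end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
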