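Package: BicScore
Title: Functional Coherence Scoring and Ranking of Biclusters
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative quality assessment of biclusters produced by any
    biclustering algorithm on gene expression data. Implements a weighted
    GO-enrichment (WE) score based on hypergeometric tests with
    Benjamini-Hochberg correction, a protein-protein-interaction coherence
    score against a confidence-thresholded STRING-style network, size-based
    bicluster filtering, unified cross-algorithm ranking with per-algorithm
    rank-section distributions, Kendall tau consistency analysis between the
    two scores, size-matched random gene-group baselines, and seeded synthetic
    generators (annotation maps, modular interaction networks, expression
    matrices with implanted coherent biclusters) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Clustering, GeneExpression, GO, NetworkEnrichment
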