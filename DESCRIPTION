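Package: hopes
Title: High-Order Path Elucidated Similarity for Multi-Omics Patient Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses patient-similarity networks built from multiple omics layers
    (e.g. gene expression, DNA methylation, miRNA) into a single global
    similarity matrix by minimizing a quadratic energy over path-0, path-1 and
    path-2 proximity constraints on per-layer K-nearest-neighbour affinities,
    solved with consensus ADMM. Includes an SNF (similarity network fusion)
    baseline, spectral and Monti-style consensus clustering, cluster and
    survival evaluation metrics (NMI, matched accuracy, chi-square association,
    log-rank, Kaplan-Meier), MCFS unsupervised feature back-projection, and a
    synthetic multi-omics benchmark generator with planted, partially
    indivisible cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
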