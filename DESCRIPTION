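Package: coexfuse
Title: Co-Expression Network and Variational Autoencoder Feature Fusion
    for Expression-Based Cancer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-step feature extraction and classification for case/control
    gene expression studies. Merges multi-batch expression matrices on shared
    gene symbols, removes batch effects with a parametric empirical-Bayes
    location/scale model, screens differentially expressed genes with a
    moderated t-statistic and Benjamini-Hochberg correction, builds a weighted
    gene co-expression network (soft-threshold selection by scale-free fit,
    topological overlap, module detection, eigengene merging, module-trait
    correlation), mines hub genes by gene significance, module membership and
    intramodular connectivity, learns a low-dimensional latent representation
    of the differentially expressed genes with a variational autoencoder, and
    fuses hub-gene expression with the latent features in a support vector
    machine evaluated on a held-out batch. Includes a synthetic-data generator
    with planted modules, hub genes, differential expression and batch effects
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
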