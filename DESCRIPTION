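Package: screproject
Title: Integrative Subcluster Analysis and Re-Projection for Single-Cell
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Connects a parent single-cell clustering to nested subcluster
    analyses through a hierarchical post-integration data model, and embeds
    subcluster granularity back onto the total-cell map by merging parent and
    child k-nearest-neighbor graphs under a weighted retention rule before
    re-computing a UMAP layout from the merged graph. Also provides
    conditional cell-proportion analysis with a selectable reference
    population, per-gene expression frequency, one-vs-rest marker detection,
    pseudobulk differential-state testing, silhouette-width evaluation of
    embeddings, and a synthetic fixture generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    cluster,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
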