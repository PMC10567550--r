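Package: epiRewind
Title: Lineage-Resolved Trajectory Reversal, Regulon Enrichment and AFM
    Stiffness Analysis for Epidermal Dedifferentiation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying wound-induced dedifferentiation of
    epidermal cells with lineage-resolved single-cell RNA-seq and atomic
    force microscopy. Implements a Seurat-style single-cell core (cell
    filtering, size-factor normalization, empirical-Bayes batch
    correction, highly variable gene selection, PCA, graph-based
    clustering, module scoring, Wilcoxon differential expression), a
    simplified principal-graph pseudotime with a directed
    pseudotime-kernel transition matrix, smoothed gene trends and gene
    module detection, the differentiation-versus-dedifferentiation
    reversal correlation statistic with a permutation null, TRRUST-format
    regulon enrichment, spherical-Hertz force-curve fitting with
    Young's-modulus maps, and skeleton-length and gliding-box lacunarity
    metrics for actin network masks. A seeded synthetic-data generator
    with planted ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    png,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    mclust,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
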