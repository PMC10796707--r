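Package: SpotPattern
Title: Spatially Variable Gene Scoring and Spatial Domain Detection for
    Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of spot-level spatial transcriptomics.
    Each gene is rendered as a grayscale image on a regular grid and scored
    by a pattern index, the product of a Significance factor (foreground
    versus background mean contrast over within-region relative dispersion)
    and a Separability factor (one minus the within-foreground-region
    variance fraction), with parametric and permutation tests of spatial
    autocorrelation (Moran's I, Geary's C) under complete spatial
    randomness and Benjamini-Hochberg FDR control. Spatial domains are
    segmented by Laplacian-smoothed principal components passed through a
    single graph-attention layer and refined by self-supervised deep
    embedded clustering with a Student's-t kernel. Includes a
    negative-binomial synthetic data generator with known domains and
    marker genes so the full workflow is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    mclust,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    EBImage,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, Spatial, GeneExpression, Clustering
RoxygenNote: 7.3.3
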