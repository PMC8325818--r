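Package: spotmap
Title: Analysis of Decoded Image-Based Spatial Transcriptomics Spot Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based spatially resolved transcriptomics data
    that arrive as a decoded spot table (one row per RNA read: gene label plus
    2D pixel coordinates). Provides read-level statistics (per-sample
    quantification, Gaussian kernel density expression maps and two-gene
    overlays, permutation-based gene-gene neighborhood enrichment, de novo
    gradient discovery and supervised 1D gradient profiling), three
    segmentation strategies (watershed nuclear segmentation of a DAPI image,
    overlapping square bins, per-read spot environments), and downstream
    analysis of the segmented count matrices (per-gene normalization, PCA
    reporting, RGB embedding maps via PCA/t-SNE/UMAP, k-means/hierarchical/
    DBSCAN clustering, and probabilistic Poisson-Bayes cell typing against
    scRNA-seq reference profiles). Seeded synthetic-tissue generators back
    the full test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    FNN,
    EBImage,
    Rtsne,
    uwot,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    jsonlite,
    yaml
Config/testthat/edition: 3
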