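Package: morphoclust
Title: Unsupervised Species Delimitation from Morphometric Data via
    Spectral Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the unsupervised discovery of species boundaries in
    morphometric character tables. Individuals measured for continuous
    morphological characters are grouped by spectral clustering of a radial
    basis function similarity matrix through the normalized symmetric graph
    Laplacian, with the number of clusters nominated by the eigengap
    heuristic over a grid of kernel widths. Discovered clusters can be
    validated against taxonomist-assigned labels (normalized mutual
    information, Rand and adjusted Rand indices) and characterized by three
    feature-selection analyses (mutual information between characters and
    clusters, character-eigenvector correlations, and cluster-versus-rest
    Welch t-tests). Ordination baselines (PCA and non-metric
    multidimensional scaling on Gower distances, each followed by k-means)
    and a synthetic species-complex generator for benchmarking are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
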