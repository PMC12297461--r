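Package: nuqloud
Title: Quantification of Multicellular Tissue Organisation from 3D Nuclear Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-type-agnostic quantification of tissue architecture from the
    3D positions of segmented nuclei. Builds adaptively restricted Voronoi
    tessellations whose boundary cells are closed by auxiliary points, derives
    fourteen per-nucleus organisational features (multi-scale shell densities,
    Voronoi geometry, neighbourhood statistics), stratifies cells into
    organisational motifs with a Gaussian mixture model and into amorphous
    versus crystalline archetypes by hierarchical clustering, calls
    expressing/non-expressing nuclei from fluorescence intensities via a
    two-component signal/noise mixture and Otsu thresholding, computes pair
    correlation functions g(r), and embeds organisational feature space in 2D
    with a staged t-SNE that supports projection of partial imaging data onto
    a stored reference. Ships synthetic point-cloud generators so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    cluster,
    mclust,
    randomForest,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
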