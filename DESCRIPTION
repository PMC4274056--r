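Package: punctanal
Title: Quantification of Synaptic Protein Puncta and Dendritic Spines in
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects fluorescent protein puncta (e.g. PSD-95 clusters) in 2D
    images of neurons by a descending multi-threshold region-growing
    algorithm that keeps adjacent bright puncta distinct, quantifies puncta
    density and intensity within user-defined dendrite regions, measures and
    classifies dendritic spines (mushroom, thin, stubby, filopodia), and
    batch-processes image sets with tabular export. Includes a synthetic
    image generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    png,
    jpeg,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
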