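Package: netcorr
Title: Network Correspondence Between Brain Atlases and Spatial Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial correspondence between user-supplied brain
    maps (thresholded statistic maps or hard parcellations) and reference
    network atlases. Computes Dice overlap matrices in a common reference
    space, assesses significance with spherical spin-test permutation nulls,
    groups networks from many atlases by spatial similarity with hierarchical
    clustering, converts metric maps to binary masks with a Gaussian-Gamma
    mixture model, and renders Network Clock, Network Radar and Overlap
    Heatmap reports from a command-line entry point. Ships an icosphere mesh
    and synthetic-atlas generator so the full pipeline runs without external
    surface templates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    yaml,
    RNifti,
    ape,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
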