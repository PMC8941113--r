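Package: hypercore
Title: Hyperbolic Disc Embedding and k-Core Percolation for Voxel-Wise
    Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise functional connectivity networks from resting-state
    BOLD time series (Pearson correlation, positive-edge thresholding under
    scale-freeness and largest-component criteria), embeds the binary graphs on the
    two-dimensional hyperbolic disc under the S1/H2 geometric network model by
    maximum likelihood with Laplacian-eigenmap initialization, quantifies angular
    coherence of labelled voxel groups with circular statistics, performs k-core
    percolation to the innermost k_max-core, and profiles the subnetwork
    composition, dominance pattern and cross-subject common core of the surviving
    voxels. Includes generators for synthetic S1 networks, block-correlated BOLD
    series, planted dense cores and multi-subject cohorts so the whole pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    RNifti,
    signal,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
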