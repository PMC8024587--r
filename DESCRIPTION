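Package: wmnet
Title: White-Matter Structural Connectome Construction and Graph-Theory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for diffusion-tensor white-matter connectomics:
    deterministic fiber tracking (FACT) on tensor volumes with the standard
    termination rules (fractional anisotropy below 0.2, turning angle above 45
    degrees), construction of FA-weighted 90-region structural connectivity
    matrices, sparsity-thresholded global and nodal graph metrics (clustering
    coefficient, characteristic path length, global and local efficiency,
    degree, nodal efficiency, betweenness) normalized against degree-preserving
    random networks and summarized as areas under the curve over a sparsity
    grid, and covariate-adjusted permutation group inference with
    false-discovery-rate control, overlap-node identification and partial
    correlation against clinical variables. A synthetic-data module generates
    tensor phantoms and two-group connectome cohorts with planted nodal effects
    so the full chain runs without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
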