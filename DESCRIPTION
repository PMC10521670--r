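Package: uniland
Title: Universal Multi-Domain Anatomical Landmark Detection in Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects anatomical landmarks in 2D radiographs with a single
    model trained jointly on several anatomically distinct datasets
    (GU2Net). A local U-shaped branch built from depth-wise separable
    convolutions splits its parameters into domain-specific channel-wise
    filters and domain-shared point-wise filters; a per-domain dilated
    convolution branch adds global context at quarter resolution, and the
    two heatmap branches are fused multiplicatively. Includes Gaussian
    heatmap encoding and argmax decoding, soft-label binary cross-entropy
    training with cyclic learning rates, mean-radial-error and
    successful-detection-rate evaluation, cross-anatomy parameter-swap
    experiments, and a seeded synthetic multi-anatomy benchmark generator
    so everything runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    jpeg,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
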