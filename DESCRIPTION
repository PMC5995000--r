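Package: octlayers
Title: Layer Segmentation and Tissue Classification for Cardiac Optical
    Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of optical coherence tomography (OCT)
    B-scans of atrial tissue. Segments each B-scan into tissue layers
    without prior structural knowledge (piecewise-linear A-line analysis
    followed by a greedy column-wise boundary search over a weighted
    gradient/intensity/shape cost), extracts sixteen per-layer optical,
    statistical and texture features, and classifies each layer into one
    of five tissue compositions with a sparse Bayesian (relevance vector
    machine) classifier. Includes a synthetic layered-speckle phantom
    generator with exact ground truth for validation, TIFF/CSV/JSON
    input-output, leave-one-group-out evaluation and HSV label overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
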