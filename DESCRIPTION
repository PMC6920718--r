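Package: bonemorph
Title: Slice-Wise and 3D Micro-CT Bone Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Global 2D slice-by-slice morphometric analysis of binarized
    micro-CT long-bone stacks and targeted 3D morphometry on
    percent-bone-length volumes of interest. Computes per-slice trabecular
    and cortical parameters as distributions over percent bone length,
    including the Trabecular Extent (Tb.E) of the distal trabecular
    structure, interpolates them onto a common 1 percent grid, and compares
    groups with pointwise t-tests and significance bands. Ships a synthetic
    long-bone phantom generator with analytic ground truth so every pipeline
    stage is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    nortest,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
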