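Package: leafmorph
Title: Phenetic Leaf Shape Features for Plant Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts botanically meaningful features from single-leaf raster
    images: a centroid-contour-distance shape signature computed at every
    boundary point, mode-consolidated peak/valley detection for lobe and sinus
    counting, vertex-angle north/south pole localisation of the leaf apex and
    base with mid-vein-width disambiguation, Centroid Contour Gradient
    curvature descriptors of the apex and base, and a margin-tooth taxonomy
    (serrate to crenulate) built on a ripples ratio and per-tooth geometry.
    Includes a ground-truth-labelled synthetic leaf generator, a nearest
    neighbour species matcher, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
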