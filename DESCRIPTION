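Package: peachvision
Title: Red Peach Detection and Sizing in Orchard Images with Linear RGB
    Color Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects red peaches in RGB orchard photographs by classifying
    every pixel according to its Euclidean distance to a set of linear color
    models (3-D lines fitted by total least squares in the normalized RGB
    cube), binarizes and cleans the resulting peach mask (small-component
    removal and hole filling), and sizes each segmented fruit with a
    two-stage focal-form ellipse fit: the difference between the major axis
    lengths before and after residual-based contour-pixel rejection yields a
    rough occlusion-range estimate. Includes a synthetic orchard-scene
    generator with exact ground truth (fruit masks, true ellipse parameters,
    achieved occlusion fractions, per-pixel classes) so the whole pipeline
    can be exercised and evaluated without field imagery, plus evaluation
    metrics (pixel-difference error, relative diameter errors) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    optparse,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
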