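Package: psyllidet
Title: Small-Object Pest Detection with Constrained Copy-Paste Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting very small insect pests (citrus psyllids and
    fruit flies) in high-resolution orchard imagery. Implements
    segmentation-guided copy-paste target enhancement with zero-overlap
    placement constraints, offline resampling, nine-block tiling with
    annotation remapping, two-scale multiscale resizing and 50%-probability
    rotation, an improved parallel-resolution detection backbone with channel
    and spatial attention, sawtooth-rate atrous spatial pyramid pooling,
    feature-pyramid fusion, three cascaded detection heads with online hard
    example mining, and average-precision evaluation. Includes a synthetic
    scene generator so the whole pipeline is exercisable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
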