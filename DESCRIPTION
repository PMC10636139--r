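Package: nucmorph
Title: Nuclear Size Morphometry and Classification for Lymphoma Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of nuclei segmentation masks for nuclear-size
    classification of lymphoma histology tiles. Converts binary segmentation
    output into uniquely labeled instances by 8-connected components labeling,
    measures per-nucleus geometry (area, convex-hull solidity, maximum
    border-pixel distance, a two-ratio circularity score, equivalent circular
    diameter), filters invalid objects by size and shape, classifies each
    nucleus as small, intermediate or large relative to a species-specific
    reference diameter, and classifies the whole image by majority vote.
    Includes brute-force grid-search optimization of the classification
    thresholds scored by macro F1 against expert consensus labels, evaluation
    utilities (Dice coefficient, IoU-based object matching, confusion
    matrices), a synthetic mask and measurement-set generator for offline
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
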