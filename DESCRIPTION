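Package: filomorph
Title: Quantification of Tip-Marked Filopodia from Semantic Label Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-segmentation measurement engines for filopodia imaged with a
    filopodial tip marker (e.g. Myo10, DdMyo7, VASP) alone or together with an
    actin label. Converts semantic label masks (background / cell body /
    filopodia tip, or background / body / stalk) plus raw fluorescence images
    into per-cell and per-filopodium measurement tables: cell morphometrics
    (area, perimeter, min-area-box aspect ratio, circularity), cortex and
    leading-edge intensity enrichment, tip-to-cortex filopodium lengths,
    traced shaft lengths along actin stalks, filopodia counts and densities.
    Includes segmentation-quality metrics (per-class IoU, F1, panoptic
    quality), a Pearson validation harness, a deterministic synthetic-scene
    generator with exact ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
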