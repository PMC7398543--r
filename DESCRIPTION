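Package: patchunet
Title: Patch-Wise Multi-Class U-Net Segmentation of Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tissue segmentation of structural brain MRI (background,
    cerebrospinal fluid, grey matter, white matter) with a patch-wise
    multi-class U-net. Slices are zero-padded to a common canvas, split into
    non-overlapping patches, segmented patch by patch and stitched back into
    full-slice label maps. Includes volume/slice I/O for NIfTI and Analyze
    formats, an invertible patch tiling layer (non-overlapping and strided
    overlapping modes), a declarative U-net builder with closed-form parameter
    accounting, an SGD training loop with momentum, the Dice/Jaccard/
    Hausdorff/MSE evaluation suite, and a synthetic four-tissue phantom
    generator so the whole pipeline trains and tests at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    oro.nifti,
    tibble,
    jsonlite,
    yaml,
    png,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    dplyr
Config/testthat/edition: 3
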