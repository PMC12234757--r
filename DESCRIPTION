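Package: recortex
Title: Surface-Guided 3D Reconstruction of Sparse Multimodal Serial Brain
    Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs continuous per-acquisition 3D cortical volumes from
    sparse, interleaved stacks of 2D post-mortem brain sections (receptor
    autoradiographs, cell-body or myelin stains). Sections are segmented into
    gray-matter masks, rigidly chained into per-slab initial volumes by
    contrast rank, aligned to a structural reference volume through an
    iterative multi-resolution 3D-then-2D deformable scheme driven purely by
    the gray-matter morphology, and missing intensities are estimated by
    sampling acquired sections onto a family of cortical depth surfaces and
    interpolating over inflated spherical meshes. Ships a synthetic phantom
    generator with known ground truth, a synthetic-contrast training-image
    generator for pluggable learned segmenters with an Otsu fallback, and the
    validation statistics (windowed and inter-section Dice, patch-based
    surface-interpolation checks, ROI intensity-accuracy, regional
    regression, permutation correlation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    withr,
    jsonlite,
    yaml,
    RNifti,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
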