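Package: pbnrr
Title: Physics-Based Non-Rigid Registration for Intra-Operative Brain Shift
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deformable registration of pre-operative to intra-operative
    brain MRI by sparse block matching with normalized cross-correlation,
    regularized by a linear-elastic tetrahedral finite-element model with
    iterative fractional outlier rejection. Includes geometric handling of
    tumour-resection cavities (maximal connected background submesh
    removal), an incremental adaptive registration loop with
    body-centred-cubic re-meshing, registration-point-driven isotropic and
    anisotropic (minimum-volume enclosing ellipsoid) mesh-sizing metrics,
    Canny-edge/Hausdorff-distance evaluation, and a synthetic brain-shift
    phantom generator with known ground-truth deformation fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
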