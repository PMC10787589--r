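Package: vesselreg
Title: Deformable Registration of Vascular Volumes with Coordinate-Based
    Neural Displacement Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic 3D deformable co-registration of longitudinal
    photoacoustic-style vascular volumes. A small multilayer perceptron with
    sinusoidal activations represents the displacement field continuously
    over the fixed-image domain; it is optimized coarse-to-fine on
    multiscale Frangi-vesselness filtered images with a patch-wise
    normalized cross correlation similarity term and a Jacobian-determinant
    regularizer. Includes volume and landmark I/O (NIfTI-1, NRRD,
    multi-page TIFF, CSV), vessel enhancement and adaptive intensity
    modulation, mask-guided coordinate sampling, evaluation metrics (PSNR,
    NCC, Dice, target registration error), a synthetic vascular-phantom
    generator with analytic ground-truth deformations, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
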