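Package: airgap3d
Title: Suppression of Air-Bubble Phase-Contrast Artifacts in Micro-CT
    Lung Volumes with a 3D Conditional GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for removing the air-bubble artifacts that
    single-distance phase retrieval leaves in phase-contrast micro-CT
    scans of paraffin-embedded lung tissue.  Provides synthetic
    lung-phantom generation with ground-truth artifact masks, a
    training-pair factory based on artifact transplantation, a 3D
    pix2pix conditional GAN (3D U-Net generator, 3D PatchGAN
    discriminator) trained with an adversarial plus L1 objective,
    checkpoint selection by relative error, PSNR and SSIM, tiled
    whole-volume inference, and watershed-based pore morphometrics
    (porosity, pore volume, extent, solidity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
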