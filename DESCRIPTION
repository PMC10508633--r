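Package: occlugen
Title: Functional Occlusal Pit-and-Fissure Depth-Image Generation for Dental
    Crown Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the functional pit-and-fissure morphology
    of posterior tooth crowns as depth images. Provides heuristic minimum-cost
    extraction of fissure feature lines on triangle meshes, entropy-tuned
    orthographic depth-map projection and its inverse, a conditional adversarial
    image-translation network (U-Net generator, patch-based discriminator) with
    L1 and perceptual-feature losses constrained by the opposing tooth, a
    parametric synthetic molar generator for end-to-end testing, and PSNR/SSIM
    image-quality plus 3-D surface-deviation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    png,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
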