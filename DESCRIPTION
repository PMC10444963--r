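Package: emgan3d
Title: Enhancing Cryo-EM Density Maps with a 3D Generative Adversarial
    Network
Version: 0.1.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org",
           role = c("aut", "cre"))
Description: Tools for modifying experimental-quality cryo-electron
    microscopy (cryo-EM) density maps toward high-resolution simulated
    maps with a 3D convolutional generative adversarial network (GAN),
    in the style of volumetric super-resolution. Includes MRC/CCP4 map
    reading and writing with axis canonicalization, trilinear grid
    resampling, min-max density normalization, simulation of density
    maps from PDB atomic models with Gaussian kernels, sliding-cube
    extraction and overlap-averaged reconstruction, generator and
    discriminator networks with content plus adversarial losses,
    alternating adversarial training, cube-level cross-correlation and
    per-residue real-space correlation (RSCC) evaluation, and a
    synthetic-fixture generator of toy protein-like structures so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
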