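Package: snakereg
Title: Weakly Supervised Deformable 3D Image Registration with Dynamic
    Snake Convolutions and Shifted-Window Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deformable registration of 3D scalar volumes (brain MRI and
    similar) with a Swin-UNet style encoder-decoder augmented by 3D dynamic
    snake convolutions, multi-fusion dense skip connections and concurrent
    spatial/channel squeeze-and-excitation gating.  A per-case instance
    optimization stage refines predicted displacement fields by Adam descent
    on a local normalized cross-correlation energy and feeds the refined
    fields back as pseudo-ground-truth supervision (weak supervision).
    Includes a synthetic phantom generator with fold-free ground-truth
    deformations, spatial-transformer warping, Jacobian-determinant folding
    analysis, Dice/SSIM/NCC metrics, NIfTI input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
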