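Package: tissuegan
Title: Virtual Staining of 3D Tissue Microstructure with Cycle-Consistent
    Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs unseen fluorescence channels of 3D liver tissue
    (bile canaliculi, sinusoids, Kupffer cells) from a single actin-mesh
    channel using unpaired image-to-image translation with cycle-consistent
    generative adversarial networks, including an Otsu-weighted
    foreground/background reconstruction loss and a paired UNet baseline.
    Ships a seeded synthetic liver-phantom generator with known tube
    geometry, patch-based training utilities, tiled whole-volume inference
    with depth-intensity profiling for deep-tissue prediction, a cube-wise
    image-quality metric suite (FID, MSE, MSLE, MAE, RMSE, PSNR, SSIM,
    MS-SSIM, cosine similarity, correlation), and bile-canaliculi network
    morphometry (skeleton graphs, radius and branch-length statistics,
    profiles along the lobule axis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
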