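Package: vegsr
Title: Weakly Supervised Field-Vegetation Segmentation via Spectral
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs four-band multispectral imagery (green, red,
    red-edge, near-infrared) from RGB field photographs with two small
    trainable image-to-image models (a concatenation-heavy convolutional
    network and a spectral self-attention network), fuses the
    reconstructed bands into a single vegetation-index or weighted-sum
    map, and thresholds that map (fixed or adaptive) into binary
    vegetation masks, so that crop/soil segmentation needs no pixel-level
    labels.  Ships a synthetic paired-scene generator with controllable
    per-band spatial misalignment ("strong noise") so every stage of the
    pipeline can be exercised offline, plus reconstruction (MRAE, SSIM,
    PSNR) and segmentation (MIoU, PA, MPA) metrics and reproducible
    end-to-end experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
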