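Package: waveseg
Title: Compressed-Domain Segmentation of Whole-Slide Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor segmentation of hematoxylin-and-eosin whole-slide images in
    a wavelet-compressed domain. Slides are cut into overlapping sliding-window
    tiles, reduced from three RGB channels to one by principal component
    analysis of the red and blue values over the Otsu tissue mask, and
    decomposed by a single-level 2-D Haar discrete wavelet transform into four
    half-resolution sub-bands. Per-sub-band tumor probability maps are
    reassembled to slide scale by overlap averaging and fused back to full
    resolution by a wavelet-weighted ensemble: each sub-band map is weighted
    per pixel by the corresponding sub-band of the tissue mask's wavelet
    transform before the inverse transform. The ensemble weights are fitted by
    exhaustive grid search on mean Dice; a scalar weighted-average ensemble,
    spatial-domain baselines, Dice/accuracy/Jaccard evaluation, and a synthetic
    pseudo-H&E slide generator with ground-truth masks are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
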