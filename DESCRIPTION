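Package: germinoct
Title: Nondestructive Seed-Germination Monitoring with Spectral-Domain OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spectral-domain optical coherence
    tomography (SD-OCT) plus camera monitoring of germinating pea seeds.
    Provides a layered-seed phantom generator with known ground truth,
    SD-OCT spectral-interferogram reconstruction, seed-coat thickness
    quantification with refractive-index correction via shape-preserving
    boundary fitting, detection of the four morphological germination
    indicators (surface wrinkles, cotyledon layers, radicle emergence,
    seed-coat cracking) with phase segmentation, camera-based seed
    morphometry, and correlation of image-derived measures against the
    gravimetric gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
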