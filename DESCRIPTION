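Package: cryptsim
Title: Simulation of Colorectal Histology Images with Sub-Cellular Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative model of healthy and cancerous (grades 1-3) colonic
    tissue in haematoxylin-and-eosin histology. Simulates crypt architecture as
    deformed ellipses, populates epithelium and stroma with phenotyped cells,
    synthesizes chromatin and lumen textures non-parametrically, builds the
    goblet-cell honeycomb of healthy crypts by Voronoi tessellation, and renders
    RGB images through a Beer-Lambert stain model together with full ground
    truth (instance label masks and per-cell/per-crypt tables). Also provides
    the matching evaluation toolkit: pixel- and object-level Dice indices,
    Gamma-distribution crypt morphometrics, 13 Haralick co-occurrence texture
    features, and affinity-propagation phenotype clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    yaml,
    jsonlite,
    png,
    tiff,
    fitdistrplus,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
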