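Package: rsatraits
Title: Two- and Three-Dimensional Root System Architecture Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and trait-extraction pipeline for comparing 2-D and
    3-D root system architecture (RSA) phenotyping of soybean-like root
    systems. Generates seeded stochastic root systems with taproot-dominant
    or highly branched architectures confined to a thin rhizobox or a
    cylindrical pot, renders them as binary photograph-like images or
    CT-like voxel volumes, segments and skeletonizes the rasters, and
    computes total root length and fractal dimension by box counting (2-D)
    or cube counting (3-D), with per-group summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    png,
    tiff,
    yaml,
    withr,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
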