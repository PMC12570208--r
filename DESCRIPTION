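Package: spimtip
Title: Single-Particle Diffraction Imaging by Multi-Tiered Iterative Phasing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale engine for single-particle X-ray diffraction imaging (SPI):
    simulates oriented, Poisson-noisy diffraction patterns of a 3D molecular
    density phantom on an Ewald-sphere detector geometry, and reconstructs the
    density (including mixtures of conformational states) by a multi-tiered
    iterative phasing (M-TIP) loop of reference slicing, exhaustive orientation
    matching, Tikhonov-regularized conjugate-gradient autocorrelation merging
    built on non-uniform FFT (type-1/type-2) operators, and iterative phase
    retrieval (error reduction / hybrid input-output with shrinkwrap support).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
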