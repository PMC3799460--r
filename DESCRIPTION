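Package: nanostain
Title: Single-Molecule Analysis of Heterogeneously Stained DNA in Nanochannels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fluorescence image stacks of single,
    intercalator-stained DNA molecules confined in nanofluidic channels.
    Generates ground-truthed synthetic populations with heterogeneous
    dye loading (wide non-equilibrated or narrow equilibrated
    distributions with conserved total dye), renders PSF-blurred,
    shot-noise-limited image stacks, fits every kymograph line with the
    box-convolved-with-Gaussian (error-function) edge profile to measure
    molecule position, extension and intensity, normalizes intensities to
    the population saturation limit, and performs the population-level
    extension-versus-dye-load analysis: fixed-width intensity binning,
    linear extrapolation of the native (dye-free) DNA extension, the
    expected-extension model line, and between-condition extension ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
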