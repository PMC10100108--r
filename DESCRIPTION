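Package: flawsopt
Title: Joint MP2RAGE UNI and FLAWS Contrast Optimization by Extended
    Phase Graph Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the MP2RAGE pulse sequence with the extended phase
    graph (EPG) formalism, including RF spoiling with quadratic phase
    cycling, T2 relaxation, diffusion attenuation of configuration states,
    transmit-field (B1+) scaling and imperfect inversion.  Propagates
    Gaussian noise by Monte Carlo through the UNI and FLAWS image
    combinations to estimate contrast-to-noise ratios, and searches
    inversion-time and flip-angle grids for protocols that deliver
    fluid-and-white-matter-suppressed (FLAWS) images while retaining most
    of the optimal UNI contrast at 7 Tesla.  Includes the UNI and FLAWS
    voxelwise combination operators with background-noise regularization,
    a synthetic brain phantom generator, NIfTI input/output, and
    image-domain contrast metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
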