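Package: nucarray
Title: Nucleosome-Array Architecture Analysis and Mesoscale Chromatin Simulation
Version: 0.1.0
Authors@R:
    person("Retina", "Chromatin Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying nucleosome-array architecture from 3D
    nucleosome pose models derived from cryo-electron tomograms: stereological
    descriptors (center-to-center distances D and N, angles alpha, beta, para),
    open-DNA linker-length calculus (O, S, E, C, L and nucleosome repeat
    length), classification of internucleosome contacts into i+/-k and trans
    categories, and a coarse-grained mesoscale Monte Carlo simulator of
    chromatin fibers with irregular experimentally derived linker-length
    profiles, linker histone, salt and implicit magnesium effects. Includes a
    calibrated synthetic-data generator emulating immature (PN1) and mature
    (PN56) retina chromatin statistics so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
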