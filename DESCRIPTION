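Package: ccsfocus
Title: Collision Cross Section Knowledge-Based Conformational Focusing for Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for focusing conformer ensembles of lipid [M-H]- anions using
    predicted collision cross sections (CCS). Reads and writes multi-frame XYZ
    conformer ensembles, computes five molecular-level descriptors (m/z, farthest
    heteroatom and farthest atom from the center of mass, heteroatom count, and
    solvent-accessible molecular surface area), trains a feed-forward neural-network
    CCS regressor, derives batch-error-based CCS filter bands, and post-processes
    focused ensembles with Kabsch-RMSD representative clustering, Boltzmann-weighted
    CCS averaging, lowest-energy candidate selection, and percent-error scoring
    against experimental reference CCS values. A synthetic fatty-acid conformer
    generator with a projection-approximation CCS oracle makes the whole workflow
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
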