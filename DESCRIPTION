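Package: ParBspread
Title: Single-Molecule Kinetics and Simulation of ParB Spreading on DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing and simulating the spreading of the bacterial
    partition protein ParB along DNA tethers. Implements the CTP-hydrolysis
    residence-time model with photobleaching censoring and its maximum-
    likelihood fitting with BIC model selection; a coarse-grained bead-spring
    model of a doubly tethered DNA molecule evolved by Langevin dynamics and
    coupled to a lattice model of ParB 1D diffusion with in-cis and in-trans
    (3D-proximity) recruitment and roadblock bypass; a Monte-Carlo null model
    of accidental colocalization; kymograph-analysis procedures (loading
    positions, residence times, recruitment detection, roadblock localization,
    arm intensities); and a synthetic-kymograph generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    mclust,
    jsonlite,
    yaml,
    tiff,
    digest,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
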