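Package: osteosim
Title: Finite-Element Simulation of Disuse Bone Remodeling and Electrical
    Stimulation After Hip Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates stress-shielding-driven disuse remodeling of the
    proximal femur after total hip arthroplasty, and the modulating effect
    of electrostatic stimulation. Provides parametric intact and implanted
    femur fixtures on tetrahedral meshes, CT-number to density/modulus
    material mapping, linear-elastic finite-element solves for daily load
    cases, an anisotropic dielectric electrostatic solve with potential
    normalization, a basic-multicellular-unit (BMU) population-kinetics
    engine with delayed resorption/filling integrals driving daily porosity
    change, and stress-ratio shielding reports with histogram summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
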