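Package: cardioem
Title: Desk-Scale Human Ventricular Electromechanics and Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order implementation of a strongly coupled human
    ventricular electromechanical modelling framework: the six-state Land
    excitation-contraction model bidirectionally coupled to buffered
    intracellular calcium, quasi-incompressible Holzapfel-Ogden orthotropic
    passive mechanics, an orthotropic active-stress tensor, strain-modulated
    monodomain conduction with stretch-activated currents, a five-phase
    Windkessel cardiac-cycle state machine with dynamic pre-stress, a
    thick-walled lumped ventricle producing pressure-volume loops, clinical
    mechanical biomarkers (EF, ESP, LFS, WT), and one-at-a-time plus Latin
    hypercube / partial rank correlation sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    deSolve,
    lhs,
    tools,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
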