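Package: poroedema
Title: Poroelastic Simulation of Inflammatory Myocardial Oedema
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: One-dimensional simulator of interstitial oedema formation in
    acute infectious myocarditis. Couples finite-strain Biot poroelasticity
    of the myocardium (neo-Hookean skeleton, Darcy interstitial flow,
    Starling capillary filtration with Hill-type lymphatic drainage) to a
    pathogen-leukocyte reaction-diffusion-chemotaxis system, discretised
    with linear finite elements and a monolithic backward-Euler
    Newton-Raphson solver. Includes the reference local and diffuse
    myocarditis scenarios, a one-at-a-time parameter sensitivity driver,
    and independent verification oracles (Terzaghi consolidation,
    spatially homogeneous kinetics, capillary-lymphatic baseline balance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
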