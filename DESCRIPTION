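Package: cosolvr
Title: Cosolvency Solubility Modeling and Mixing Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for equilibrium solubility of a solid solute
    in binary cosolvent + water mixtures measured over a temperature grid.
    Converts raw gravimetric solubilities to mole fractions, computes ideal
    solubility from fusion thermodynamics, activity coefficients, and ideal,
    excess and net mixing thermodynamic functions, blends Hansen solubility
    parameters across mixture compositions, and fits and compares five
    cosolvency models (van't Hoff, Apelblat, Yalkowsky-Roseman,
    Jouyban-Acree and Jouyban-Acree-van't Hoff) with percent RMSD and R
    squared diagnostics.  Ships the piperine in Transcutol-HP + water
    solubility grid as a packaged example dataset, and a seeded synthetic
    grid generator for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
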