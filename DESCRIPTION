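Package: hbridge
Title: Substituent-Increment Analysis of Intramolecular Hydrogen-Bridge
    Proton Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing proton-transfer energetics in salen-type
    tri-ring aromatic Schiff bases carrying two symmetric O-H...N hydrogen
    bridges.  Reads O-H scan profiles and extracts the three bridge
    parameters (activation energy, second minimum and their difference),
    fits the additive composite-substituent-effect model
    EA = EBC + IE-SUB + IE-STER + IE-DIST (and the second-minimum
    analogue) from mono-substitution grids, predicts bridge parameters for
    new substitution patterns, scores approximation error, builds
    proximal-by-distal heatmap matrices with spread statistics and
    charge-difference diagnostics, and generates synthetic double-well
    scan datasets with known ground truth so that every stage of the
    pipeline is testable without quantum-chemistry computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
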