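Package: bvctools
Title: Simulation and Classification of Boundary Vector Cell Firing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing boundary-coding neurons recorded (or
    simulated) during open-field foraging. Provides geometric models of
    standard testing environments (walled and unwalled circles, squares,
    platform arrays, inserted barriers), a generative simulator of
    boundary vector cell (BVC), head direction and boundary-off firing
    with inhomogeneous-Poisson spike trains, locational firing rate maps
    and directional polar plots, the barrier-elicited field-repetition
    criterion for classifying BVCs, Skaggs spatial information and
    selectivity with a matched-bin correction for inhomogeneous sampling,
    a Monte Carlo null for field-peak distances, and theta-modulation
    scoring of spike-train autocorrelograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
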