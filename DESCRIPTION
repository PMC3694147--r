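Package: pidkit
Title: Primary Ion Depletion Kinetics Analysis for Proton Transfer
    Reaction Mass Spectrometry
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for primary ion depletion kinetics (PIDK) studies in
    proton transfer reaction mass spectrometry (PTR-MS). Provides a
    drift-tube ion-molecule reaction-network simulator reproducing the
    depletion/replenishment phenomenology of hydronium chemical
    ionization, isotopologue pattern computation and bounded elemental
    composition search for nominal m/z interpretation, ion-intensity
    trace containers with transmission correction and normalization,
    phase segmentation and three-way fragment classification,
    isotopologue-deviation analysis, composite-signal decomposition,
    reaction-order estimation, inert-gas-stripping slope confirmation,
    reduced-field (E/N) utilities, and a seeded synthetic-trace
    generator with full ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
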