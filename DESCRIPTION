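Package: oxypulse
Title: Simulation and Single-Cell Analysis of the OxyR Oxidative Stress Regulon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how Escherichia coli regulates its OxyR-controlled
    oxidative stress regulon under hydrogen peroxide treatment. Provides a
    deterministic ODE model of the OxyR redox switch with enzymatic H2O2
    scavenging, growth-rate coupling, reporter genes and plasmid copy-number
    dynamics; a seeded generator of mother-machine-style single-cell track
    tables (mechanistic or template-driven with known ground truth);
    growth-corrected promoter-activity and expression statistics for such
    tracks; and a windowed rank-test classifier that sorts genes into
    sustained/transient up/down regulation categories and splits upregulated
    genes into pulsatile and gradually responding classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
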