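Package: poreflux
Title: Microsensor Porewater Profile Analysis for Hypoxic Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of depth-resolved microsensor profiles (O2, pH, H2S)
    from marine sediments. Computes total dissolved sulfide from paired pH
    and H2S readings via the first dissociation constant of hydrogen
    sulfide, detects the oxygen penetration depth and the sulfide horizon,
    estimates diffusive fluxes across the sediment-water interface with
    Fick's first law using porosity-corrected molecular diffusivity plus an
    abundance-dependent biodiffusivity, and partitions sediment oxygen
    consumption into sulfide-oxidation-driven and residual components.
    Includes a steady-state synthetic profile generator with analytic
    ground truth for parameter-recovery testing, and a config-driven
    pipeline with a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
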