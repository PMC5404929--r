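Package: snarepore
Title: Energetics and Electrophysiology of SNARE-Crowded Fusion Pores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium free-energy model of the fusion pore formed between
    a protein-scaffolded bilayer nanodisc and a planar membrane in the
    presence of zippering SNARE proteins, together with a single-pore
    patch-clamp analysis pipeline: zero-phase filtering and decimation,
    current-burst and flicker idealization, conductance-to-radius
    conversion, Boltzmann inversion of pore-size distributions into
    apparent free-energy profiles, two-state conductance clustering, and a
    dilation-probability sigmoid versus SNARE copy number.  Includes a
    staged parameter-fitting recipe for the model and a synthetic-recording
    generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    mclust,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
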