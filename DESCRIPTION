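Package: promtune
Title: Thermodynamic Tuning of the Dynamic Range of Ligand-Inducible Bacterial Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanics modelling of sigma70-dependent transcription
    initiation at ligand-inducible Escherichia coli promoters. Represents
    combinatorial -35 x -10 promoter libraries, computes occupancy-based
    transcription rates under activators and repressors, fits per-site binding
    free energies to plate-reader data by least squares on log rates with
    gauge fixing, normalizes raw plate measurements to relative promoter units
    (RPU), evaluates multi-input transcriptional AND gates, and generates
    seeded synthetic plate-reader datasets emulating combinatorial library,
    dose-response and logic-gate experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
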