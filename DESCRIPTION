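Package: ssmrMAR
Title: Single-Cell Mass Accumulation Rate Analysis for Serial SMR Drug-Sensitivity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs single-cell buoyant-mass-versus-time traces from
    per-sensor detection events produced by a serial suspended microchannel
    resonator (sSMR) array, calibrates raw signal to absolute buoyant mass
    using spiked polystyrene beads, estimates per-cell mass accumulation
    rates (MAR) and MAR per mass by linear least squares, and classifies
    treated versus control cell populations with a two-class linear
    discriminant projection, ROC/AUC analysis, and Welch's t-tests with
    Bonferroni correction to call samples drug-sensitive or resistant.
    Includes a synthetic sSMR experiment generator with ground truth so the
    whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
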