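Package: ddtrap
Title: Droplet Digital TRAP Telomerase Activity Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and quantification pipeline for the droplet digital
    telomere repeat amplification protocol (ddTRAP). Converts droplet
    fluorescence amplitudes into Poisson-corrected template concentrations
    with confidence intervals, applies control-anchored thresholding,
    no-template-control background correction and cell-equivalent
    normalization, and provides the downstream analyses used with the assay:
    replicate coefficient-of-variation tables, limiting-dilution linearity,
    single-cell telomerase positivity calling, four-parameter logistic
    dose-response (IC50) fitting and stimulation time-course comparison.
    Includes a seeded synthetic-plate generator that emulates the droplet
    reader (zero-inflated per-cell product counts, saturating extension
    kinetics, multinomial droplet partitioning, two-band fluorescence
    amplitudes and Poisson background contamination) so the full workflow is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
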