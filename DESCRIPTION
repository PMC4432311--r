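Package: qpianiso
Title: Scattering Anisotropy and Recurrence Statistics from Quantitative
    Phase Images
Version: 0.1.0
Authors@R:
    person("QPI", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Computes the optical scattering anisotropy factor (g) of tissue
    from quantitative phase images via the scattering-phase theorem, with an
    independent Fourier-optics oracle that recovers g by fitting the
    Henyey-Greenstein phase function to the simulated far-field angular
    scattering distribution.  Includes mosaic stitching for tiled phase
    images, a noise/error-propagation model for g, a synthetic-data module
    (Gaussian random fields, oriented fiber textures with controllable
    fragmentation, tissue-core layouts, matched patient cohorts and
    post-surgical PSA series), and patient-level statistics: per-patient
    aggregation, Welch tests, ROC/AUC with threshold analysis, CAPRA-S
    scoring, a biochemical-recurrence rule and PSA-stratified comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
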