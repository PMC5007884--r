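Package: ddpcrval
Title: Single-Laboratory Validation of Droplet Digital PCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the absolute quantification of nucleic-acid copy number
    concentrations by droplet digital PCR (ddPCR) and for the single-laboratory
    validation of such methods. Converts droplet-level fluorescence amplitudes or
    positive/accepted droplet counts into copy number concentrations via the
    Poisson partition estimator, applies well quality-control and threshold/rain
    classification rules, and computes the full method-validation statistics:
    nested one-way ANOVA precision (repeatability and run-to-run variation),
    root-mean-square pooling, trueness against certified reference materials,
    assay and threshold-setting variance components, a combined expanded
    measurement-uncertainty budget (coverage factor k = 2), limit of detection
    and quantification assessment, and robustness comparisons. Closed-form
    stochastic-effect predictions (Poisson sampling and binomial partition
    components) and a droplet-plate simulator with configurable rain, run and
    assay effects make the entire pipeline testable without instrument data.
    Certified values for the ERM-AD623 plasmid reference materials are bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
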