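Package: glxquant
Title: Quantification of Glomerular Endothelial Glycocalyx Imaging Readouts
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the glomerular endothelial glycocalyx and
    filtration-barrier function from three kinds of imaging readouts:
    automated fluorescence line-profile peak-to-peak measurement of
    glycocalyx thickness from two-channel (lectin + membrane) confocal
    micrographs, with Gaussian peak fitting, SD/SNR quality-control
    exclusion and hierarchical loop-glomerulus-subject averaging;
    transmission electron microscopy grid-intersection morphometry
    (glycocalyx thickness and coverage, basement-membrane and podocyte
    widths, linear densities); and apparent albumin permeability (Ps'_alb)
    estimated from the first-minute decline of capillary-lumen fluorescence
    in trapped glomeruli. A synthetic-data module generates all three input
    kinds with known ground truth (blurred ring images, cohort manifests,
    annotation tables, decay traces) for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
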