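Package: spermwall
Title: Wall-Relative Sperm Trajectory Kinematics, Tracking and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for sperm motility near the uterine wall in
    fluorescence time-lapse microscopy. Simulates ground-truth sperm
    trajectories near a straight wall and renders them into two-channel
    image stacks; detects sperm-head spots and links them into tracks with
    gated linear-assignment linking and gap closing; computes the CASA
    kinematic parameters VCL, VSL and LIN together with the straight
    line-to-sideward movement ratio (SWR); fits a straight-line wall model
    from boundary pixels and derives per-track wall distance and angle
    covariates; and provides the exact one-tailed binomial test with
    one-sided Clopper-Pearson bound for wall-contact turning direction plus
    fixed-effects regression of log-transformed kinetic parameters on wall
    covariates.
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
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
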