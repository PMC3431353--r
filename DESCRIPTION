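Package: tugsim
Title: Stochastic Tug-of-War Simulation and Trajectory Analysis of
    Bidirectional Cargo Transport Along Microtubules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transport of intracellular cargoes (such as
    melanosomes) driven along microtubules by two opposing teams of
    elastically coupled molecular motors (kinesin-like forward and
    dynein-like backward steppers), using an overdamped Langevin equation
    for the cargo and stochastic stepping, attachment and detachment
    kinetics for the motors. Includes the full trajectory-analysis
    pipeline used for single-particle tracking data: selection of
    processive periods, 40-point segmental velocities with speed and
    linearity filters, pulling/attachment-state-resolved velocity
    histograms, spatial motor distributions and the pulling-motor ratio,
    detection of long-term direction reversions with saturating
    exponential rise-time fits, and four-Gaussian fits of multimodal
    velocity distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
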