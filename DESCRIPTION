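Package: stimmap
Title: Stimulation-Site and Network Mapping for Subthalamic Deep Brain
    Stimulation Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for locating beneficial ("sweet") and
    detrimental ("sour") subthalamic stimulation sites from deep brain
    stimulation cohorts, and for mapping the structural and functional
    networks that predict clinical outcome. Includes a finite-difference
    volume-of-tissue-activated (VTA) model with a four-compartment
    conductivity volume, voxel-wise probabilistic stimulation mapping with
    nonparametric statistics, discriminative fibre filtering on streamline
    sets, seed-based functional-connectivity R-maps from a normative
    connectome, leave-one-out cross-validation with covariate adjustment,
    and a fully synthetic cohort generator with planted spatial and network
    effects so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
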