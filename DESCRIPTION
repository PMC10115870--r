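Package: dysmap
Title: Focal and Connectome-Projected Mapping of Transient Brain Disruption
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-wise spatial inference from sparsely sampled transient
    disruption data such as direct cortical electrical stimulation. Stimulation
    loci are transformed either into Gaussian density volumes (focal arm) or
    into connectivity volumes projected through a voxel-level structural
    connectome (dysconnectome arm), then analysed with a repeated-measures
    mass-univariate general linear model with compound-symmetry whitening,
    one-tailed t contrasts and permutation-based peak-level family-wise error
    control. Includes an ROI-versus-voxel-wise predictive benchmark with
    bootstrapped classification metrics and averaged ROC curves, a synthetic
    cohort and connectome generator for end-to-end validation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
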