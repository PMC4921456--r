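Package: voxnet
Title: Voxel-Level Functional Brain Network Reconfiguration Between Rest and Task
Version: 0.1.0
Authors@R: person("M.", "Keller", email = "mkeller.neuro@gmail.com", role = c("aut", "cre"))
Description: Builds and compares voxel-wise functional connectivity graphs from
    resting-state and task fMRI time series. Provides a synthetic data generator
    (labeled toy brain volumes, block-structured correlated voxel time series
    with AR(1) noise, global signal and motion artifacts, and an Iowa Gambling
    Task payoff simulator), a preprocessing chain (volume discard, motion
    scrubbing, band-pass filtering, nuisance and global-signal regression),
    density-controlled network construction under the N = K^S rule, local and
    global efficiency metrics, hub-topography comparison via a Jaccard-index
    permutation test, spherical ROI masks for the default-mode and
    fronto-parietal networks, and group statistics (repeated-measures ANOVAs
    with partial eta squared and a linear mixed model with AR(1) errors
    predicting task performance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    nlme,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
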