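Package: drivelapse
Title: Driving-Task Simulation and Sustained-Attention Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sustained attention from continuous
    performance on a simulated lane-keeping (car driving) task. Provides a
    1-D lateral kinematic simulator of the task (curved and straight road
    segments, outward curve drift, edge clamping), closed-loop driver models
    with attention-lapse schedules for generating synthetic cohorts with an
    age-dependent skill gradient, CSV readers/writers for session
    recordings, age-stratified boxplot statistics of lane-keeping error,
    Tukey-fence outlier masking with sustained-run (>= 1 s) detection to
    localise attention loss and recovery in time, and k-means clustering of
    binned error trajectories with scree-based selection of the number of
    clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    patchwork
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
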