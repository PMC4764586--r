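Package: sptmap
Title: Single-Particle Tracking Analysis of mRNA and Ribosome Mobility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping translation hot-spots in live cells from
    single-particle tracking data. Simulates Brownian, two-state switching,
    corralled and tethered trajectories with ground truth; detects and links
    fluorescent spots in movie stacks; computes mean-square-displacement
    curves, apparent diffusion coefficients, and one- and two-component
    cumulative-distribution-function fits of displacement distributions;
    builds gridded local-diffusion and localization-density maps; partitions
    trajectories by focal-adhesion compartments; detects mRNA-ribosome
    co-movement with an area-normalized distance-distribution null; and
    annotates per-step motion states with a pooled two-state diffusion
    hidden Markov model.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
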