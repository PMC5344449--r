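Package: nirstroop
Title: Simulation and Group Analysis of fNIRS Conflict (Stroop) Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multichannel continuous-wave functional
    near-infrared spectroscopy (fNIRS) recordings from block-design conflict
    paradigms (gesture/word and color/word Stroop tasks). Provides a
    synthetic-data generator with a forward optical model, conversion of
    optical density to chromophore concentration changes via the modified
    Beer-Lambert law, preprocessing (dead-channel rejection, wavelet
    detrending, zero-phase low-pass filtering, PCA spatial filtering of
    global systemic components, downsampling), probe-to-MNI registration and
    channel-to-voxel interpolation, first-level GLM estimation with a
    canonical double-gamma HRF, group-level cluster inference calibrated by
    sign-flip Monte Carlo permutation, a dual voxel/channel significance
    criterion, and behavioral reaction-time statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    knitr,
    rmarkdown
Config/testthat/edition: 3
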