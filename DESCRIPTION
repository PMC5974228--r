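Package: msranet
Title: Multi-Seed Region Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds region-by-region functional connectivity graphs from 4D
    BOLD time-series volumes parcellated by an integer label atlas. Implements
    the pseudo-directed multi-seed region analysis (MSRA), in which the mean
    time-course of a small automatically placed seed in each region is
    correlated with every brain voxel, significant correlations are selected
    by false discovery rate and averaged per target region, yielding an
    asymmetric correlation matrix; and two symmetric comparators, seed-region
    cross-correlation (SRCC) and regional cross-correlation on first principal
    components (RCCA). Provides Gaussian smoothing, low-pass filtering and
    global-signal regression preprocessing; average-degree graph thresholding
    with modularity community detection at a target community count;
    method-comparison metrics (overall correlation, Jaccard index, ICA
    co-activation index, reproducibility variance with bootstrapped median
    confidence intervals); a paired network-based statistic (pNBS) with
    permutation family-wise-error control for detecting connectivity
    modulation between two sessions in paired control/experimental designs;
    and a synthetic-data generator producing toy atlases and BOLD studies with
    community-structured covariance and planted paired-session modulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
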