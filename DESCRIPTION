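Package: freqdc
Title: Frequency-Resolved Voxel-Wise Degree Centrality for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise degree centrality (DC) maps of resting-state
    BOLD fMRI data within contiguous frequency sub-bands. Provides ideal
    (rectangle-window) DFT band-pass filtering, thresholded-correlation degree
    mapping with z-normalization, white-matter/CSF nuisance regression,
    gray-matter-volume covariate residualization, nonparametric cluster-level
    group inference by max-cluster-size permutation, cross-band spatial map
    similarity with Fisher r-to-z comparisons, cluster-wise clinical score
    correlation, and a seed-deterministic synthetic cohort generator with
    planted frequency-specific hubs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
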