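Package: fcasym
Title: Seed-Based Resting-State Connectivity, Hemispheric Asymmetry, and
    White-Matter Asymmetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for seed-based resting-state functional connectivity
    (RSFC) analysis with an emphasis on hemispheric laterality: voxelwise
    Pearson correlation maps against bilateral seed regions, Fisher r-to-Z
    transformation, left-right flipping of statistical maps on a symmetric
    grid, per-subject asymmetry contrasts, voxelwise one-sample, paired and
    two-sample t maps, and Monte-Carlo cluster-extent correction in the
    style of AlphaSim. Also included are diffusion-tensor fractional
    anisotropy (FA) computation from eigenvalue maps, region-of-interest FA
    summaries and the (right-left) asymmetry index, Stroop and symptom-scale
    group statistics, sphere-ROI extraction, and imaging-behavior Pearson
    correlation with Bonferroni adjustment. A synthetic-data module
    generates two-group datasets (4D BOLD, FA, behavioral tables) with
    planted connectivity, laterality, group and correlation structure so
    the full pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
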