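Package: netchange
Title: Single-Subject Functional Connectome Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects longitudinal changes in a single subject's resting-state
    functional brain network from two scans of denoised ROI-averaged time
    series. Builds binarized correlation networks (|r| above a cutoff),
    computes six nodal graph metrics (degree, clustering coefficient,
    betweenness centrality, nodal global efficiency, local efficiency,
    average path length), tests per-ROI pre/post metric differences against
    a kernel-density resampling null with empirical p-values and
    Benjamini-Hochberg FDR control, and screens ROIs whose metric values
    deviate from the cross-ROI mean by multiples of the standard deviation.
    Includes a block-covariance AR(1) time-series simulator with plantable
    connectivity changes for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
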