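Package: ChromDyn
Title: Chromatin Locus Diffusion and Continuous-Photobleaching Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-particle-tracking trajectories of nuclear
    loci (telomeres, centromeres, gene loci) and continuous-photobleaching
    traces. Simulates fractional Brownian motion ensembles with localization
    noise and rigid nuclear motion; corrects whole-nucleus drift and in-plane
    rotation; computes time-averaged mean square displacements and estimates
    anomalous-diffusion parameters at single-locus and ensemble level with
    the mean-logarithmic-square-displacement (MLSD) procedure; quantifies
    scanned nuclear territories and internal/peripheral locus positioning
    via convex hulls; and extracts bound/free protein fractions from
    continuous-photobleaching intensity traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, CellBiology, SingleCell
RoxygenNote: 7.3.3
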