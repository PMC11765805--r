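Package: replifork
Title: Quantification of Replication Fork Stalling and Restart from
    Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring replication-fork stalling and restart
    kinetics in live-cell time-lapse microscopy. Implements diffuse-pool
    ROI photometry that converts the depletion of freely diffusing PCNA
    or RPA1 into the fraction of protein bound at replication foci,
    stoichiometric conversion of bound fractions into complexes per fork
    and ssDNA nucleotides using proteome copy numbers, exponential
    half-time fitting of stalling and restart trajectories, FRAP
    normalization with two-component (diffusing/bound/immobile)
    decomposition, and single-focus kymogram measurement. Includes a
    synthetic movie generator with fully known ground truth (piecewise
    exponential bound-fraction schedules, Gaussian foci, Poisson and read
    noise, drift, photobleaching, and FRAP bleach events) so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
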