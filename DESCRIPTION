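Package: cycleproc
Title: Preprocessing of Cycle-Based Multiplexed Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Multiplex", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to turn raw per-cycle mosaic acquisitions from cyclic
    multiplexed fluorescence imaging (PhenoCycler/CODEX-style instruments)
    into analysis-ready data: point-spread-function synthesis and
    Richardson-Lucy deconvolution, extended depth of field projection,
    cycle-interpolated shading correction, blank-cycle autofluorescence
    subtraction, translation-only inter-cycle registration, grid stitching
    into per-channel mosaics, nuclei segmentation, per-cell measurement, and
    export to CSV, FCS 3.1 and ImageJ ROI archives. Includes a synthetic
    acquisition simulator with known ground truth for end-to-end testing,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
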