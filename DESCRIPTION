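Package: epiproc
Title: Single-Subject FMRI Preprocessing, Regression Modelling and Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A self-contained, block-based pipeline for single-subject
    functional MRI: slice-timing correction, rigid-body motion estimation
    and correction with single-step resampling through concatenated
    transforms, multi-echo optimal combination, automasking, per-voxel
    percent-signal scaling, RETROICOR/RVT physiological regressors, and a
    general linear model with HRF bases, bandpass-as-regressors, motion
    censoring and degrees-of-freedom bookkeeping.  A pipeline compiler
    turns a block+option specification into a validated execution plan
    and a fully commented, provenance-preserving runnable script, and an
    integrated quality-control battery produces scalar metrics, derived
    maps and a static HTML review.  Synthetic phantoms with known ground
    truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
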