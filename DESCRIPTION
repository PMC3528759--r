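Package: sssflow
Title: Pulsatile Cerebrospinal Fluid Flow in the Cervical Spinal
    Subarachnoid Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline comparing 4D phase-contrast MRI style
    quantification of cerebrospinal fluid (CSF) flow against rigid-wall
    computational fluid dynamics in the cervical spinal subarachnoid space.
    Provides parametric healthy-like and Chiari-like geometries, a forward
    simulator of velocity-encoded phase-contrast MRI (VENC aliasing, phase
    noise, vascular confounders, nerve-root velocity deficits), ROI flow
    quantification (waveforms, peak velocities, stroke volume, zero-net-flow
    offset), a flow-rate-constrained sectionwise pulsatile Stokes solver with
    Womersley-type analytic references and grid/time-step independence
    machinery, cardiac-gated tissue-motion masking, and cohort-level
    MRI-versus-CFD comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    RNifti,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
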