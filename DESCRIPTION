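Package: fpetconn
Title: Metabolic Connectivity Analysis for Constant-Infusion FDG-fPET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional PET (fPET)
    acquired under constant [18F]-fluorodeoxyglucose infusion, simultaneously
    with BOLD fMRI. Provides frame-grid arithmetic for 16-second list-mode
    binning, radioactive decay correction and quadratic plasma-curve fitting,
    the separable spatio-temporal gradient filter that converts cumulative
    glucose uptake into an instantaneous uptake-change signal, ROI time-series
    extraction against an integer parcellation, within-subject metabolic and
    haemodynamic connectivity with Fisher-z group averaging, across-subject
    static metabolic covariance, block-wise connectome stability and
    filter-width sweeps, and motion quality control from rigid-body
    realignment parameters. A synthetic-data generator emulates the
    acquisition (plasma input function, planted inter-regional correlation
    structure, point-spread blur, imaging noise, rigid motion, BIDS-like
    layout) so that every stage is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
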