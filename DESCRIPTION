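Package: aslcov
Title: Spatial Coefficient of Variation Analysis for Arterial Spin
    Labelling Perfusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the spatial coefficient
    of variation (sCoV) of cerebral blood flow (CBF) maps from
    pseudo-continuous arterial spin labelling (pCASL) MRI, a surrogate
    marker of arterial transit time. Provides a synthetic digital-phantom
    cohort generator with group-dependent transit-time prolongation, a
    single-compartment kinetic forward model for pCASL difference
    signals, white-paper CBF quantification with local linear-regression
    partial volume correction, ROI sCoV and mean-CBF metrics, classical
    cohort statistics from summary data, and order-restricted Bayesian
    ANCOVA model comparison via encompassing priors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
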