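Package: cyclofit
Title: Binding Analysis of Drug-Cyclodextrin Inclusion Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative characterization of host-guest
    inclusion complexes between a poorly soluble drug and a cyclodextrin:
    Higuchi-Connors phase-solubility fitting and A_L classification with
    association constants and derived free energies, mass-action speciation
    and global multiwavelength spectrophotometric titration fitting with
    stoichiometry model selection by residual-trend analysis, Voigt
    multi-band deconvolution of the O-H stretching envelope with two-state
    van 't Hoff hydrogen-bond thermodynamics and isosbestic-point detection,
    DOSY diffusion-based bound-fraction estimation, chemical-shift
    displacement tables, and the supporting assay arithmetic (viability,
    LDH release, cumulative permeation with sampling-dilution correction,
    HPLC calibration with LOD/LOQ).  A synthetic-data module generates
    inputs with the statistical structure each analysis assumes, so the
    whole chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
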