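Package: erpsource
Title: Distributed Source Reconstruction and Mass-Univariate Statistics for ERP Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the full analysis chain of multi-subject event-related
    potential (ERP) experiments with a 2x2 repeated-measures design: a three
    concentric sphere volume-conductor forward model with a compartment-labelled
    spherical source space; mass-univariate two-way repeated-measures ANOVA over
    electrodes and time points with Benjamini-Hochberg false discovery rate
    control, post hoc contrast maps and Z-transforms; LORETA-style minimum-norm
    inverse solutions with a graph-Laplacian smoothness prior, combined across
    anatomical-constraint models by Bayesian model averaging with evidence-based
    Occam pruning; and second-level group analysis of inverse-solution maps via
    local-FDR mixture binarization, conjunction proportions, signed subtraction
    conjunctions and sign-flip permutation thresholds.  A synthetic-study
    generator plants dipolar component sources (N170/P200/N250/N400) in labelled
    compartments so that every stage is testable end-to-end without recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
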