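Package: rvatlas
Title: Statistical Shape Atlas and Strain Analysis of the Systemic Right Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational shape and function analysis of the
    systemic right ventricle in hypoplastic left heart syndrome. Provides a
    synthetic cohort generator (segmentation stacks, cine contours and
    analytic ground truth), mesh personalization of short-axis label volumes
    into corresponded endo/epicardial surfaces, Simpson slice-summation
    volumetry with allometric body-surface-area indexing, a principal
    component shape atlas with mode-wise group comparison, feature-tracking
    style Lagrangian strain and strain-rate analysis, and the cohort
    statistics (t-tests, chi-squared, ANOVA with Bonferroni correction,
    two-way random absolute-agreement intraclass correlation) needed to
    assemble group comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
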