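Package: cmdyn
Title: Disentangling Cell Migration from Membrane Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plasma-membrane protrusion and retraction dynamics
    from time series of segmented binary cell masks, constructs Corrected
    Membrane Dynamics (CMD) - a cell-speed-independent measure of membrane
    activity obtained as the residual of the linear fit of Dynamic Cell
    Area on Cell Speed - and statistically classifies image-derived single
    cell features by the structure (quintile-stratified Wilcoxon archetype
    testing) and specificity (Kruskal-Wallis plus canonical variate
    analysis) of their association with Cell Speed versus CMD. Includes a
    synthetic generator for mask movies and feature tables with planted
    ground truth so every stage of the analysis is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
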