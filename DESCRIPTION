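Package: chronocomp
Title: Comparing Divergence-Time Estimates Between Molecular Dating Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing time-calibrated phylogenies (chronograms)
    produced by different molecular dating methods. Reads timetrees from
    Newick and annotated NEXUS dialects (BEAST MCC-style and MCMCTree
    FigTree-style node metacomments carrying uncertainty intervals), matches
    homologous nodes between trees over the same taxa, converts calibration
    densities to hard age bounds, and computes per-dataset comparison
    statistics: the slope and coefficient of determination of the regression
    through the origin, mean squared error, the mean normalized node-age
    difference, coverage of one method's point estimates by another method's
    uncertainty intervals, and normalized uncertainty widths. Linear
    feature-importance models relate dataset characteristics to method
    disagreement, and a synthetic-study generator (Yule timetrees with
    planted multiplicative bias and node-age noise) supports end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    caret,
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
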