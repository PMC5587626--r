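Package: spinsys
Title: Peak List Registration Analysis and Spin System Grouping for Protein NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preprocessing protein NMR peak lists ahead of resonance
    assignment. Implements a peak list registration analysis algorithm that runs
    in pairwise mode (aligning two peak lists and estimating per-dimension
    translation offsets and standard deviations) and in self mode (estimating
    within-list peak positional variance from a single peak list with multiple
    peaks per spin system), a variance-informed DBSCAN grouping algorithm that
    clusters peaks into spin systems using a chi-square distance cutoff, and an
    iterative pipeline that combines both to peel off successive variance
    populations within one peak list. Also provides a peak list simulator that
    builds assigned peak lists from chemical-shift tables via declarative
    spectrum descriptions, adds single- or two-source Gaussian positional noise,
    and scoring utilities that compare recovered spin systems against truth.
    Readers and writers for Sparky, AutoAssign-style and JSON peak list formats
    are included, along with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
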