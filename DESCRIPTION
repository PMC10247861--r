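Package: transamp
Title: Identifying Transient Amplifiers of Selection for death-Birth Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and analysing population structures (graphs)
    that transiently amplify natural selection under death-Birth updating.
    Implements the coalescing-random-walk effective population size test for
    weak-selection amplification, a guided iterative edge-removal search from
    regular input graphs with normalized-Laplacian spectral filtering and
    cospectral deduplication, spectral-dynamics analysis of the search
    (smoothed spectral densities and a pseudometric distance), constructors
    and amplification scans for barbell, dumbbell, Moebius-ladder-bell and
    antiprism-bell graph families, and exact and Monte-Carlo fixation
    probabilities with amplifier/suppressor/transient classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
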