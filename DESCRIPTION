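Package: coanpipe
Title: Haplotype-Based Coancestry, Fine-Scale Clustering and Admixture Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-scale population-structure analysis from phased
    haplotype panels: expected-length chromosome painting under a
    Li-and-Stephens haplotype-copying model, coancestry-matrix clustering with
    a Dirichlet-multinomial partition model and MCMC (including clustering on
    haplotype sharing with external donor groups via a calibrated block
    matrix), a bootstrap test for excess cross-cluster coancestry, sum-to-one
    non-negative ancestry profiles with pseudo-individual bootstrap intervals,
    spatially smoothed ancestry fields on a regular grid, and admixture dating
    from the exponential decay of ancestry covariance with genetic distance.
    Includes a synthetic-panel generator with known demes, drift, geography and
    dated admixture pulses so every stage can be exercised against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
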