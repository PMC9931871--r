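Package: accperc
Title: Accessibility Percolation on Cartesian Power Genotype Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and Monte-Carlo tools for accessibility percolation in
    House-of-Cards fitness landscapes whose genotype space is a Cartesian power
    of an allele graph. Computes critical fitness differences (beta*) and
    critical walk lengths from divergence-weighted means of matrix-exponential
    log-entries, classifies accessibility setups as regular, semi-regular or
    irregular via Martinsson's function, reproduces closed-form thresholds for
    complete, no-return and path allele graphs and for the amino-acid graph
    induced by single-nucleotide substitutions under the standard genetic code,
    and validates the analytic formulas against exact small-instance oracles
    and seeded House-of-Cards simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    Biostrings,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    jsonlite,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
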