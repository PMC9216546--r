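Package: ratesnap
Title: Inferring Biochemical Rate Functions from Static Snapshot Covariability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers how one molecular component regulates another's production
    rate from static joint snapshots of their abundances, without temporal
    information. At stationarity the joint distribution P(x2, x3) must satisfy
    probability flux-balance (cut) equations whenever the production and
    degradation reactions of the downstream component are qualitatively known;
    ratesnap inverts these equations with a smoothness-regularized,
    non-negativity-constrained least-squares solver to recover the production
    rate function f(x2) over the observed states. Includes an exact
    Doob-Gillespie simulator for three-component test motifs with Hill-type
    regulation, a brute-force truncated chemical-master-equation solver used as
    an oracle, measurement-noise models (additive, relative, binomial
    undercounting with exact rescaling correction), a cross-validated
    constant-rate model-selection step, and quality metrics (probability
    weighted inference error and a noise-propagation importance measure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
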