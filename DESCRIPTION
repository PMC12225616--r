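Package: dyadsim
Title: Monte Carlo Evaluation of Dyadic Discrepancy Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for comparing idiographic dyadic discrepancy
    estimators: the raw score difference (RSD), empirical-Bayes slopes from a
    two-level random-coefficient model with fixed measurement-error variance
    (EBD), and latent difference factor scores from a two-indicator structural
    equation model (SEM). Provides the factorial study design (intraclass
    correlation, number of dyads, member reliabilities, discrepancy effect
    size and its variance), a synthetic dyad generator, outcome-prediction
    regressions, a metric battery (bias, reliability, power, coverage,
    R-squared bias), eta-squared meta-ANOVAs of the simulation cells, and
    diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
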