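Package: idascreen
Title: Outcome-Blinded Initial Data Analysis for Multivariable Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic, outcome-blinded data screening ahead of multivariable
    regression modelling. Given a rectangular dataset, a data dictionary with
    variable roles, and a screening plan, computes missing-data summaries
    (item missingness, complete-case cascades, missingness-pattern
    dendrograms), univariate descriptions (quantiles, Gini mean difference,
    spike-at-zero detection), transformation selection via normal-scores
    correlation (pseudo-log, cube root), multivariate diagnostics (Spearman
    and Pearson correlation matrices, variable clustering, variance inflation
    factors, redundancy analysis), and rule-based recommendations for
    amendments to a statistical analysis plan - all without ever evaluating
    predictor-outcome associations. Includes a generator for synthetic
    clinical-laboratory-like data with planted structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    ggplot2,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
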