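Package: unilorenz
Title: Universal Parametric Lorenz Curves and Closed-Form Gini Indices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a universal four-parameter functional form for the Lorenz
    curve -- a weighted combination of a linear segment, a power (exponential)
    component and a Pareto-implied component -- to non-negative size
    distributions, including datasets containing zeros and extreme
    one-large/many-equal distributions. Provides the closed-form Gini index of
    the fitted curve, the three-parameter SCS and four-parameter S comparator
    models, constrained multistart least-squares estimation, five
    goodness-of-fit statistics (R-squared, MSE, MAE, maximum absolute error,
    and Theil's information inaccuracy measure), empirical Lorenz-curve
    construction with discrete Gini indices, synthetic scenario generators,
    and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lhs,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
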