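Package: mbpower
Title: Power Benchmarking for Multivariate Differential Abundance in
    Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based benchmarking of statistical techniques that
    detect multivariate differential abundance between two groups of
    metagenomic samples. Provides a heavy-tailed synthetic community
    generator, spike-in "disease models" targeting rare, medium, common and
    correlated feature sets, six families of global test statistics
    (a modified multivariate Metastats count statistic, penalized logistic
    regression, distance-based regression via the PERMANOVA pseudo-F,
    principal component and partial least squares regression with
    cross-validated R-squared, and a Hill-number diversity family test),
    resampling-based empirical null calibration, and empirical power
    estimation with standard errors over repeated assessments.
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
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
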