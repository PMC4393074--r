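Package: fdmoments
Title: Moment-Based Estimation of False-Discovery Counts Under
    Intergene Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of false discoveries in large-scale
    two-group differential-expression testing when test statistics are
    correlated.  A one-parameter empirical density of pairwise gene-gene
    correlations is estimated from the expression residuals by
    Fisher-transform deconvolution, propagated through second- and
    third-order moments of the null z-value histogram counts, and
    connected to inference by a maximum-entropy fit of the joint
    distribution of the rejection-tail count and the null center-area
    count.  Conditional distributions of the false-discovery count given
    the observed center count, exceedance-bound discovery control, and a
    Gamma-Gamma Gaussian-copula simulator of correlated all-null
    expression matrices are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
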