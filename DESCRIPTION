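Package: dclr
Title: Distributed Conditional Logistic Regression for Multi-Site Binary
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates covariate-outcome associations for binary outcomes
    observed across many clinical sites without pooling patient-level data.
    The pairwise conditional logistic likelihood (all discordant
    case-control pairs within a site) eliminates site-specific intercepts
    and is therefore robust to heterogeneous baseline risks.  The package
    provides the pooled gold-standard estimator, fixed-effect
    inverse-variance meta-analysis, and a one-round distributed surrogate
    likelihood estimator (dCLR) in which sites exchange only coefficient
    vectors, gradients and Hessians; U-statistic sandwich and within-site
    bootstrap inference; a heterogeneous multi-site synthetic data
    generator; a simulation harness with relative-bias summaries and violin
    plots; and a file-based command line interface so each protocol step
    can run at a different institution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
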