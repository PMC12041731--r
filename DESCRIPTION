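Package: twinnet
Title: Twin-Design Comparison of Regularized Partial Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and comparison of Gaussian graphical models in
    like-sex twin samples. Provides graphical-lasso estimation over a
    100-model penalty path with extended-BIC selection, rank-based
    (nonparanormal) Gaussianization of skewed variables, strength and
    expected-influence centrality, case-dropping and nonparametric
    bootstrap stability diagnostics, a permutation network comparison
    test of global strength and structure, and an orchestrated
    three-level twin comparison design (co-twin reassignment, zygosity,
    gender) together with a synthetic twin-pair generator with known
    ground-truth network structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
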