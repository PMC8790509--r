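Package: testleteq
Title: Testlet Response Theory Models for Equating Testlet-Based Test Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and calibration tools for equating test forms built
    from testlets under the non-equivalent groups with anchor test (NEAT)
    design. Implements the two-parameter logistic model (2PLM), its testlet
    extension (2PTM), the graded response model (GRM), and the graded
    response testlet model (GRTM); generates synthetic NEAT form pairs and
    response data with person-by-testlet random effects; performs concurrent
    calibration by multiple-group marginal maximum likelihood EM with
    bifactor-style dimension reduction and EAP ability scoring; and
    summarises equating error as bias, standard error of equating (SEE),
    and RMSE across Monte Carlo replications.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
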