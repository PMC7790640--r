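Package: sizedemog
Title: Size-Structured Demography from Capture-Mark-Recapture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian estimation of size-dependent survival, growth,
    recapture and fecundity from capture-mark-recapture data on a terrestrial
    salamander (Cormack-Jolly-Seber likelihood with a log-log hazard link,
    von Bertalanffy growth in increment form with latent-size imputation, and
    a normal egg-count model), an integral projection model built from the
    posterior, and perturbation-based elasticity analysis of the asymptotic
    population growth rate. Includes an individual-based simulator of the
    cover-board survey design for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    coda,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
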