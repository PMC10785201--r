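Package: healthspan
Title: Multi-State Life Tables for Disability-Free Life Expectancy in Ageing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates total life expectancy and life expectancy lived with and
    without disability in older-adult panel cohorts.  Provides deterministic
    scoring of healthy-lifestyle factors, five disability definitions and a
    socioeconomic vulnerability index from raw survey items; chained-equations
    multiple imputation (predictive mean matching and logistic draws); latent
    class growth analysis to group subjects by lifestyle or socioeconomic
    trajectory; Gompertz proportional-hazards estimation of the four transition
    intensities of an illness-death model with recovery from interval-censored
    panel data (midpoint episode splitting or an exact interval likelihood);
    weighted group-specific transition rates; multi-state life tables over ages
    65 to 115; percentile bootstrap confidence intervals; and a synthetic-cohort
    generator with a microsimulation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    flexsurv,
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
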