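Package: fltpet
Title: Dynamic 18F-FLT PET Analysis of Hepatocellular Carcinoma Response to
    Chemoembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification of dynamic 18F-fluorothymidine (FLT) PET studies of
    hepatocellular carcinoma treated with transarterial chemoembolization
    (TACE). Provides standardized-uptake-value (SUV) quantification over
    regions of interest, construction of a metabolite-corrected image-derived
    arterial input function, forward simulation and weighted multistart
    fitting of the reversible two-tissue compartment model with derivation of
    the net influx constant Ki, kinetic spatial filtering of physiologic liver
    background by time-activity-curve template classification, lesion response
    classification from percent SUV change with concordance (Cohen kappa) and
    rank statistics, and a seeded four-dimensional digital liver phantom and
    cohort simulator for validating every pipeline stage.
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
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
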