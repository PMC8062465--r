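Package: birn
Title: Quantification of Nanoparticle Internalisation with Binary
    Ratiometric Nanoreporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for binary ratiometric nanoreporter (BiRN)
    experiments: a phenomenological two-module pH-threshold model of the
    probe's fluorescence, titration fitting for transition pH, response
    width and activation ratio, linear calibration between the OFF-ON to
    always-ON (O/A) intensity ratio and the turn-ON (endocytosis)
    percentage with inversion, dual-channel ratio imaging with binary
    masking and puncta counting, mono-exponential internalisation and
    release kinetics with four-parameter logistic dose-response fitting,
    conversion of fluorometry to tissue accumulation in percent injected
    dose per gram and intracellular dose, and cohort stratification with
    exposure-response correlation. A synthetic-data module generates
    titrations, calibration plates, dual-channel tissue images,
    pulse-chase time courses and subject cohorts with ground truth so the
    full pipeline is testable without imaging hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
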