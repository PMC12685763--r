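Package: contactscape
Title: Resource-Driven Contact Inference from Wildlife GPS Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers conspecific contacts from GPS collar telemetry and
    quantifies how landscape resources shape contact probability. Provides
    quality control for raw fixes, continuous-time movement models
    (IID/OU/OUF) fitted by exact Gaussian likelihood with AICc selection,
    variogram-based range-residency checks, autocorrelation-adjusted kernel
    home ranges, 1-minute conditional-mean track interpolation, dyadic
    proximity-based contact detection and event grouping, availability
    (non-contact) sampling, distance-to-resource covariates, a weighted
    mixed logistic contact resource selection function with dyad random
    slopes and a fixed large intercept variance, multiple correspondence
    analysis of contact-event typologies, and a synthetic landscape and
    movement generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
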