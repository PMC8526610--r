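Package: railbat
Title: Event-Triggered Disturbance Analysis of Bat Activity Around Passing Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transient suppression of bat echolocation activity by
    passing trains. Provides a synthetic generator for train schedules, bat-pass
    point processes with post-train suppression, and calibration audio with known
    ground truth; event processing (bat-pass segmentation, train length/speed
    estimates, inter-train gaps); calibrated sound-pressure-level extraction with
    distance standardisation and train-noise frequency grouping; fixed-duration
    before/after/between interval datasets; negative binomial count models with
    an optional site random intercept, univariate screening, all-subsets AICc
    ranking with full model averaging, and pairwise incidence-rate-ratio
    contrasts; and disturbance time-budget (exposure) reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
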