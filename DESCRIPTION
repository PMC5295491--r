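Package: coawave
Title: Noninvasive Central Hemodynamics and Wave Intensity Analysis for
    Repaired Aortic Coarctation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for noninvasive central hemodynamics from
    single-cycle aortic area and flow waveforms: central systolic blood
    pressure by exponential pressure-area calibration against brachial
    oscillometric pressures, local pulse wave velocity (Bramwell-Hill) and
    characteristic impedance, arterial resistance and total arterial
    compliance by two-element windkessel tuning, wave intensity analysis with
    forward/backward wave separation and backward-compression-wave detection,
    a reduced one-dimensional pulse-wave simulator of coarctation scenarios,
    and a synthetic cohort generator with known ground truth for
    parameter-recovery testing. Results are returned as tibbles with broom
    style tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
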