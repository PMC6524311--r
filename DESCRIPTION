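Package: iplmotion
Title: Dose Coverage of Intraprostatic Lesion Boosts Under Intrafraction
    Prostate Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the dosimetric impact of intrafraction prostate motion
    on spherical simultaneous integrated boosts (SIB) to intraprostatic
    lesions (IPL). Provides a drift-diffusion generator of synthetic
    intrafraction displacement trajectories whose variance grows linearly in
    elapsed time, per-axis and radial displacement summary statistics,
    closed-form sphere-sphere overlap coverage fractions of the lesion by the
    boost (and vice versa) as a function of displacement and safety margin,
    Monte Carlo dose-volume histograms with D_V and V_D queries, and a
    reproducible end-to-end pipeline that writes tidy report tables and a run
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
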