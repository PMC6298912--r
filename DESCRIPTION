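Package: ceusquant
Title: Bolus-Kinetic Quantification of Contrast-Enhanced Ultrasound Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies organ perfusion from contrast-enhanced ultrasound (CEUS)
    bolus wash-in cine loops. Extracts region-of-interest time-intensity curves,
    fits a lognormal bolus kinetic model by bounded multi-start nonlinear least
    squares, derives the nine standard wash-in perfusion parameters (peak
    enhancement, wash-in rate, time to peak, rise time, area under the curve,
    mean transit time, perfusion index, wash-in perfusion index, wash-in area
    under the curve), and compares two study arms per timepoint with Welch's
    unequal-variance t-test, including tests computed directly from published
    group summaries. A synthetic-data module generates time-intensity curves,
    speckled cine loops, and full two-arm longitudinal study tables emulating a
    murine ovarian CEUS study, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
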