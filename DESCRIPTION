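Package: dustrisk
Title: Inhalation Health Risk and Endpoint Impact Assessment for
    Heavy-Metal Dust Storms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: US EPA-style inhalation exposure and risk assessment for
    trace elements carried by dust-storm particles: average daily intake,
    hazard quotients and hazard index, incremental lifetime cancer risk,
    chromium speciation, a 95 percent upper confidence limit
    exposure-point concentration for PM10, WHO guideline exceedance
    summaries, and ReCiPe-style endpoint characterization (DALY and
    species.yr per gram of dust). Includes a seeded synthetic generator
    for multi-site dust compositions and PM time series so the whole
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
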