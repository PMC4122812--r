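Package: pollenonset
Title: Predicting Tree Pollen Season Onset from Pre-Season Temperature
    Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for forecasting the start of Alnus (alder), Corylus
    (hazel) and Betula (birch) airborne pollen seasons from short-term
    temperature fluctuations. Implements 5-day trailing running means of
    daily maximum or mean temperature, detection of pre-season "local
    minima" (a dip preceded by at least two strictly falling and followed
    by at least two strictly rising days), cumulative-sum determination of
    pollen season start days with early/moderate/late season typing,
    construction of the binary training cases linking local minima to
    onset within a ten-day window, maximum-likelihood logistic onset
    models with Wald, odds-ratio and likelihood-ratio diagnostics,
    forecast verification against held-out years, and a synthetic
    weather/pollen generator for end-to-end testing and parameter-recovery
    studies. Reference coefficient sets and season-start observations from
    two decades of monitoring in Krakow, Poland are bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
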