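Package: defoprecip
Title: Observational Attribution of Tropical Precipitation Change to Forest Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the sensitivity of precipitation to tropical
    forest-cover loss from gridded observations. Implements multi-scale block
    aggregation of fractional forest loss, bilinear regridding of monthly
    precipitation cubes, a moving-window nearest-neighbour estimator that
    contrasts each deforested pixel with its less-deforested neighbours,
    median sensitivity estimation with seasonal and forest-loss-binned
    variants, and projection of future precipitation change under linear,
    capped and piecewise (binned) response assumptions. A seeded synthetic
    generator produces forest-cover histories, biome masks and monthly
    precipitation cubes with a known injected deforestation-precipitation
    sensitivity, so the full pipeline is verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
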