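Package: soilrisk
Title: Human Health Risk Assessment of Heavy Metals in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptive statistics, Pearson correlation screening and
    USEPA-style human health risk assessment for per-sample heavy-metal
    concentration tables from contaminated soils. Computes chronic daily
    intake by ingestion, inhalation and dermal contact, hazard quotients
    and hazard indices for non-carcinogenic risk, and incremental lifetime
    cancer risk, with a seeded Monte Carlo propagation of uncertainty in
    intake rate, body weight, concentration and slope factor. Includes a
    synthetic concentration-table generator that reproduces target
    per-metal moments inside stated bounds so the whole pipeline is
    testable without raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
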