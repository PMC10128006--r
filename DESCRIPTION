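Package: synflux
Title: Community Stoichiometric Flux Analysis of Cellulose-to-Methane
    Synthetic Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits species-level overall reactions to net metabolite
    accumulations measured in synthetic anaerobic communities that degrade
    cellulose to methane. Non-negative least-squares estimation of reaction
    extents, pathway-exclusion scans that enumerate degenerate equal-fit
    flux distributions, flux-range (variability) analysis, inference of
    producer-to-consumer cross-feeding fluxes, higher-order (tertiary)
    synergy quantification across culture compositions, and carbon and
    electron-equivalent balance sheets of fermentation products. Includes a
    seeded synthetic-data generator for endpoint and daily-cumulative
    observations so every pipeline stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
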