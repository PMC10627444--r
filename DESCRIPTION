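Package: marshres
Title: Multi-Metric Resilience Assessment for Tidal Marshes Under Sea Level Rise
Version: 1.0.0
Authors@R: person("Marsh", "Resilience Team", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes thirteen geospatial resilience metrics per marsh unit
    (core-to-edge ratio, unvegetated edge ratio, buffered land-cover
    fractions, soil erodibility, tidal range, marsh elevation relative to
    tidal datums, hardened shoreline, shoreline sinuosity, marsh migration
    ratio under inundation scenarios, and wetland connectedness), converts
    them to decile-rank scores within three categories (current condition,
    vulnerability, adaptive capacity), combines them into category, total
    resilience, and ordinal management-category outputs, and summarizes
    results at arbitrary grouping scales.  Includes a seeded synthetic
    landscape generator so the whole pipeline is testable without external
    geospatial downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
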