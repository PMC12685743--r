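Package: sargquant
Title: Satellite and In Situ Quantification of Pelagic Sargassum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies floating Sargassum from multi-band Rayleigh-corrected
    reflectance imagery: computes the Alternate Floating Algae Index (AFAI),
    masks land and cloud with distance buffers, extracts connected patches of
    Sargassum-containing pixels, converts background-corrected AFAI to
    sub-pixel fractional coverage and wet biomass, and aggregates fractional
    density into 0.5-degree monthly and annual composites and regional time
    series on an ecological-year axis. Companion tools analyse neuston-net tow
    logs (weighted arithmetic mean densities and morphotype proportions),
    compare time periods with two-sample F and t tests, and summarise monthly
    climatologies with quartile box statistics. A synthetic-scene and tow-log
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    geosphere,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
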