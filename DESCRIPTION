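Package: tracern2o
Title: 15N Tracer Estimation and Source Partitioning of N2O Production
    Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates volumetric nitrous oxide (N2O) production rates from
    15N tracer incubation time series using delta-notation isotope
    arithmetic and linear regression of labelled N2O against time,
    partitions the rates into fungal, bacterial, and nitrification sources
    from selective-inhibition (chloramphenicol) treatments, and
    depth-integrates the fungal contribution between the oxycline and the
    oxic-anoxic interface of an oxygen minimum zone. Includes a synthetic
    incubation generator with a realistic noise model for end-to-end
    validation, and a Poisson model for the detectability of a
    single-copy fungal gene in a metagenome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
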