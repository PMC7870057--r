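Package: ldassay
Title: Limiting-Dilution Inference for Transfection Efficiency and
    Selectable-Marker Loss
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical inference for limiting-dilution plating assays
    under the Poisson single-hit model. Estimates the number of
    independent stable transfectants in a transfection from positive-well
    counts on one or more plates (joint binomial likelihood across
    plating fractions), and the per-cell probability of selectable-marker
    loss from replica plating (zero-truncated-Poisson/binomial compound
    model). Confidence intervals are obtained by grid inversion of
    simulated plating distributions (parametric-bootstrap confidence
    belts). Includes Fisher exact comparisons between conditions,
    per-generation loss conversion, synthetic-data generators for
    coverage validation, delimited-table input/output and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
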