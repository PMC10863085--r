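Package: growthfit
Title: Growth Curve Fitting and Parameter Extraction for Plate-Reader Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parse wide-format microbial growth tables (plate-reader OD600 or
    CFU time series), blank-correct, smooth and log-transform them, and extract
    growth parameters (maximum specific growth rate, lag time, exponential-phase
    boundaries, doubling counts, yield) by fitting modified Logistic and
    Gompertz models in the Zwietering parameterization, by the Easy Linear
    sliding-window heuristic, or from a manually chosen window. Includes a
    synthetic-curve simulation study for validating the fitters and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readxl,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
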