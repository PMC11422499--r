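Package: phytoptics
Title: Bio-Optical Processing of Phytoplankton Culture Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipelines that turn raw flow-through optical
    instrument streams and filter-pad scans from phytoplankton cultures
    into an optical fingerprint library: temperature/salinity- and
    scatter-corrected hyperspectral absorption and attenuation,
    particulate backscattering via single-angle chi-factor conversion and
    three-angle volume-scattering-function integration, particle size
    distributions on a 32-bin logarithmic grid, filter-pad
    pathlength-amplification absorption with detrital spectrum fitting,
    and pigment ratios with propagated uncertainty.  A seeded synthetic
    instrument simulator renders matched pure-water, unfiltered and
    0.2-micron-filtered runs from known ground truth so every stage is
    verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
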