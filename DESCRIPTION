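Package: myostates
Title: Resting Myosin Metabolic-State Analysis from Mant-ATP Chase Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the disordered-relaxed (DRX) and super-relaxed (SRX)
    states of myosin in single permeabilized muscle fibers from loaded
    Mant-ATP chase fluorescence recordings. Fits double-exponential decays to
    normalized fluorescence traces, derives per-fiber myosin ATP consumption
    and temperature-sensitivity ratios, quantifies equatorial and meridional
    reflections from 1D small-angle X-ray diffraction profiles, and provides
    the accompanying hierarchical (animal-mean) group statistics and
    proteomics differential-expression / PTM z-score analyses. Includes a
    synthetic-data module that generates every input the pipeline consumes,
    so the full analysis is testable end to end without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    car,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
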