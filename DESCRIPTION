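Package: volcap
Title: Volumetric Capnography Signal Processing for Spontaneous Breathing
Version: 0.1.0
Authors@R:
    person("Volcap", "Maintainers", email = "volcap@example.org", role = c("aut", "cre"))
Description: Toolkit for processing synchronized airflow and mainstream CO2
    partial-pressure recordings sampled on a uniform 10 ms grid, as produced
    by portable volumetric capnographs. Segments spontaneous breathing into
    respiratory cycles by flow reversal with hysteresis, computes per-cycle
    ventilatory parameters (inspiratory and expiratory times and volumes,
    end-tidal CO2, peak expiratory flow, CO2 volume eliminated per breath),
    builds volumetric capnograms and fits the phase III slope on the 40-80%
    tidal-volume window, fits linear static-bench sensor calibrations with
    95% confidence and prediction intervals, compares per-breath parameter
    tables between devices with Mann-Whitney tests, and generates seeded
    ground-truth-labelled synthetic spontaneous-breathing records for testing
    every stage without hardware. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
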