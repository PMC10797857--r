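Package: cpscore
Title: Conditional Performance Score for Sample Size Recalculation in
    Two-Stage Adaptive Designs with Binary Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating sample size recalculation rules in two-stage
    adaptive clinical trial designs with binary endpoints. Implements the
    normal approximation test and its one-dimensional parameterization by the
    standardized treatment effect for two proportions, inverse normal
    combination testing with Pocock-type local levels and binding futility,
    five common stage-two recalculation rules (group sequential, observed
    conditional power, restricted observed conditional power, promising zone,
    and optimization function), exact Bernoulli simulation of the interim test
    statistic, and the conditional performance score combining location and
    variation of conditional power and total sample size. Includes global
    performance measures (power, mean sample size), simulation presets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
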