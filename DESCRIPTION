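Package: strikerisk
Title: Vessel Strike Encounter Risk Simulation for Large Whales
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic simulation of lethal vessel strikes on large whales
    on a regular spatial grid. Composes a two-dimensional random-movement
    encounter kernel, regional dive-depth exposure, a vertical dive-avoidance
    geometry, and a speed- and size-dependent lethality logistic into
    per-transit mortality draws, aggregated by Monte Carlo bootstrap to annual
    mortality by vessel size class. Includes readers and validators for
    AIS-derived transit summaries, monthly whale density surfaces and
    bathymetry, a synthetic scenario generator for end-to-end testing, a
    "slow-all" speed-restriction counterfactual with shared random draws, and a
    one-at-a-time sensitivity sweep runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
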