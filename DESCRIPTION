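Package: bsnkit
Title: Design Models for In-Body Chemical Sensor and Biosensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic and Monte Carlo tools for sizing body chemical sensor
    and biosensor networks (BSNs) in which injected sensors drift with the
    blood and transmit measurements to wearable data collectors worn on the
    skin. Models sensor transport from blood velocity or volumetric flow,
    the collision-aware probability of a successful readout per transmission
    opportunity, expected readout curves as a function of sensor count, the
    optimal and feasible sensor counts for a required readout budget, and a
    smart-sensor-selection search for the minimum deployment. Bundled case
    studies cover tennis elbow, runner's knee, shin splints, and heel
    inflammation monitoring, with scenario configs, CSV/JSON reports, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
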