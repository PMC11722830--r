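Package: liftzone
Title: Lifting Hand-Location Estimation and ACGIH TLV Risk-Zone
    Classification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates two-handed lifting hand locations (vertical height V
    and horizontal distance H, in metres) from five body-worn inertial
    measurement units using a sagittal-plane link-chain model, classifies
    each lift into the twelve ACGIH Threshold Limit Value lifting zones and
    three grouped risk levels (low, medium, high), and evaluates
    classification accuracy with agreement grids, confusion matrices and
    precision/recall/F-scores.  Includes a drift-correcting complementary
    filter for segment inclination, a rule-based lifting-event detector, a
    forearm-ratio anthropometric model, and a seeded synthetic lifting-trial
    simulator that emulates a 10-subject, 360-trial laboratory design with
    motion-capture-style ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
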