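Package: kneedegen
Title: Template-Based Knee Compartment Mechanics and Cartilage Degeneration Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized finite-element-style forecasting of knee
    osteoarthritis progression from simple anatomic and gait measurements.
    Scales a layered hexahedral template mesh of the medial and lateral
    tibiofemoral compartments to a subject's anatomy, constructs stance-phase
    compartmental joint contact forces (even sharing, neural-network load
    sharing, or neural-network load sharing and peaks), computes maximum
    principal solid stress fields with a documented instantaneous
    elastic-foundation contact surrogate for fibril-reinforced cartilage,
    applies age-dependent tensile failure thresholds to quantify degenerated
    cartilage volume in the central joint region, and classifies knees into
    Kellgren-Lawrence groups with ROC/AUC statistics including a native
    DeLong test. Includes a seeded synthetic cohort generator, joint space
    width and narrowing measurement from frontal-plane contours, a
    FEBio-dialect solver deck exporter, and an end-to-end experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
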