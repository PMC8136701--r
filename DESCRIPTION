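Package: aedcover
Title: AED Coverage, Hotspot Placement and Relocation Analysis for
    Out-of-Hospital Cardiac Arrest Registries
Version: 0.1.0
Authors@R:
    person("Vaud", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates automated external defibrillator (AED) placement
    against historical out-of-hospital cardiac arrest (OHCA) locations.
    Computes straight-line nearest-AED distances and coverage under a
    100 m rule, stratified coverage summaries (municipality class and
    home/public location), greedy detection of uncovered-OHCA hotspots
    with proposed AED placements and before/after coverage deltas, and
    coverage-preserving relocation of redundant AEDs in over-covered
    areas.  Includes a seeded synthetic scenario generator with planted
    hotspots and overlays so the full pipeline is testable without
    registry data, plus CSV/GeoJSON readers and writers and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
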