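Package: iaakit
Title: Analysis of Honeybee Antennal Positioning Under Airflow and Optic Flow
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how flying honeybees set the position of their
    antennae (the inter-antennal angle, IAA) as a function of frontal airflow
    and front-to-back optic flow. Provides two-camera DLT calibration and 3D
    landmark reconstruction, IAA kinematics and airspeed/groundspeed vector
    algebra, circular descriptive statistics and a permutation implementation
    of Moore's paired circular test, sigmoid characterization of the
    IAA-vs-airspeed response with dynamic-region detection, optic-flow
    saturation-threshold detection with change-prediction scoring against a
    scrambled-data null, combined-cue offset and regime analyses, a crossmodal
    speedometer calibration procedure, and a synthetic-data generator that
    reproduces the statistical structure of tethered and free-flight
    high-speed video recordings so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
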