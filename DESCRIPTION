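Package: ventsim
Title: Closed-Loop Simulation of a Turbine-Based Emergency Ventilator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A behavioural simulator for a low-cost turbine-driven emergency
    ventilator. Models the pneumatic circuit (turbine, servo-actuated pressure
    release mechanism, one-way valve and passive pilot-operated PEEP valve)
    coupled to a single-compartment test lung, the firmware's feed-forward plus
    proportional/PID motor-speed control, the PRVC, PCV and SIMV ventilation
    mode state machines with alarms and patient-circuit disconnection
    detection, pressure-sensor calibration and an outlier-band sensor
    filtration statistic, battery energy and runtime accounting, and the
    fixed-width telemetry frame codec used between firmware and GUI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
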