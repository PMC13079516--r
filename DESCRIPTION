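Package: cdtime
Title: Comparator-Based Dynamical Model of Interval Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference toolkit for a comparator-based
    dynamical model of subjective time. Provides the subjective-time gain
    factor kappa and its deviation/precision measures, closed-form and
    numerical solutions of the damped restoring dynamics that pull the
    gain back to veridical timing, composition of cerebellar, basal
    ganglia and cortical gains with duration-dependent weights and a
    cerebellar comparator correction, disorder-regime presets with
    challenge/restoration scenarios and parameter interventions, forward
    models of interval reproduction, temporal bisection, rhythmic tapping
    and an EEG spectral-peak readout, and estimators that recover the
    dynamical parameters and gains from synthetic observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
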