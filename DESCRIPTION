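Package: propulsim
Title: Simulation and Analysis of Handrim Wheelchair Propulsion Across
    Testing Modalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying handrim wheelchair propulsion measured
    overground, on a treadmill, and on a stationary ergometer under
    standardized power output. Provides a synthetic-data generator for
    instrumented-wheel signals, coast-down velocity traces and
    breath-by-breath gas exchange with closed-form ground truth;
    push-by-push kinetic and spatiotemporal outcomes (push time, cycle
    time, contact angle, fraction of effective force, torque, work,
    negative work per cycle, power output); rolling-resistance estimation
    and cross-modality power standardization; physiological outcomes
    (energy expenditure, gross mechanical efficiency, heart rate);
    agreement statistics (ICC(2,1) with F-based confidence intervals,
    repeated-measures ANOVA or Friedman omnibus tests, paired
    comparisons with effect sizes); and one-dimensional statistical
    parametric mapping of time-normalized push profiles with
    random-field-theory and permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
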