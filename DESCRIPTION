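Package: ventpower
Title: Mechanical Power Modelling and Minimization for Controlled
    Mechanical Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the mechanical power delivered to a passive,
    linear single-compartment respiratory system under volume-controlled
    ventilation with constant inspiratory flow, decomposed into elastic,
    resistive and intrinsic-PEEP components. Computes the steady-state
    intrinsic PEEP from incomplete exhalation, minimizes total or elastic
    mechanical power over tidal volume and I:E ratio under a fixed
    alveolar minute ventilation, derives the closed-form elastic-power
    optimum at twice the anatomic dead space, and produces ventilator
    settings recommendations. Includes an independent breath-by-breath
    time-domain simulator used to cross-validate the closed-form
    expressions, plus a command-line interface for batch runs and
    power-versus-volume curve generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
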