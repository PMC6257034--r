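Package: mangofirm
Title: Kinetic Modelling of Mango Firmness Loss Under Temperature and
    Ethylene
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and hierarchical estimation of a
    first-order kinetic model of mango softening. Firmness decays towards
    a residual level through the action of a cell-wall-degrading enzyme
    pool that is steadily induced by a constant internal ethylene driver
    and degrades by first-order turnover; all rate constants follow
    Arrhenius temperature dependence. The package evaluates the model in
    closed form and by ODE integration under piecewise temperature
    scenarios or logged temperature traces, computes the ethylene factor
    (EF) at the mean storage temperature, fits the model to long-format
    repeated-measures firmness data with staged attribution of variation
    (common, per-batch, per-fruit parameters) by indexed nonlinear least
    squares, and generates seed-controlled synthetic datasets emulating
    the batch structure of acoustic-firmness storage trials on 'Keitt'
    and 'Kent' mangoes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
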