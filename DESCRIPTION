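Package: glufrac
Title: Glucose-Insulin Dynamics Under Caputo-Fabrizio Fractal-Fractional Operators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a three-state glucose-insulin regulatory model driven
    by Caputo-Fabrizio fractal-fractional operators with constant or
    time-varying fractal exponent. Implements the exponential-kernel operator
    ingredients (normalization constant, variable-order kernel coefficients),
    fixed-order and variable-order Newton-interpolation integrators, linear
    state-feedback control with eigenvalue-shift gain tuning, and stability
    diagnostics: Lipschitz contraction constants, Hyers-Ulam stability
    constants, Benettin Lyapunov spectra, and normalized root-mean-square
    error. Ships the full set of simulation scenario presets with
    configuration and trajectory input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
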