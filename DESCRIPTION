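Package: shadematch
Title: Computer Color Matching of Dental Ceramics with a GA-Initialized
    Backpropagation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts dentin porcelain powder recipes (mass fractions of five
    VITA-style shade powders) from a target tooth color measured in CIELAB.
    Implements a three-layer backpropagation network trained by full-batch
    gradient descent with a momentum term, an adaptive learning efficiency
    schedule with step rollback, and a flat-area gradient factor that
    de-saturates the activation to escape error-surface plateaus; initial
    weights and thresholds can be optimized by a real-coded genetic algorithm
    with roulette-wheel selection. Includes a damped Gauss-Newton
    (Levenberg-Marquardt) trainer for small dense networks, hidden-layer
    sizing by the square-root rule plus trial and error, a BP versus GA+BP
    comparison harness, a synthetic porcelain-mixing data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
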