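Package: startlemod
Title: Normative Cost-Minimisation Model of Startle Reflex Modulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing the startle reflex as cost-minimising
    behaviour under Bayesian beliefs about impending physical impact.
    Provides parametric families for the direct and opportunity costs of
    the startle response and of a blow, a grid-plus-refinement solver for
    the cost-minimising startle magnitude with numeric audits of the
    model's assumptions, Bayesian computation of blow probability from
    forward-model factors (fear-potentiated startle, CS-alone, and
    prior-probability manipulations), a continuous blow-magnitude
    extension contrasting full-distribution coding with a sparse
    expectation-coding approximation, trial-level conditioning and
    extinction simulations (including the medium- versus high-magnitude
    footshock dissociation), a catalogue of qualitative-prediction
    scenarios, and cost-curve figure generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    patchwork,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
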