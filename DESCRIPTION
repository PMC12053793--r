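Package: metarange
Title: Metapopulation Colonisation-Extinction Dynamics at Species Range Limits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a species' geographic range limit is
    consistent with metapopulation dynamics. From two-snapshot plot-occupancy
    surveys the package classifies colonisation and extinction events, models
    their spatial gradients with binomial regression (optionally with a
    spatially correlated random effect using an exponential-decay covariance,
    fitted by Laplace approximation), predicts equilibrium patch occupancy
    from the Levins model n* = c/(c + e) with a bootstrap confidence
    envelope, and compares the prediction against observed occupancy. A
    spatially explicit stochastic patch-occupancy simulator generates
    two-survey datasets with known ground truth for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    glmmTMB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
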