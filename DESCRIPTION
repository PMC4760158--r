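Package: sizetransfer
Title: Plankton Size Diversity and Biomass Trophic Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline linking plankton size structure at two trophic levels
    to biomass trophic transfer. Converts two-axis particle measurements
    (FlowCAM, ZooSCAN) to ellipsoidal biovolume and carbon biomass, estimates
    kernel-density Shannon-analogue size diversity of prey and predator
    communities, computes the log10 predator/prey biomass ratio used as a
    trophic transfer proxy together with production-ratio and mass-ratio
    covariates, prepares depth-integrated environmental predictors, and fits
    random-intercept linear mixed models ranked and selected by AICc.
    Includes a station-structured synthetic survey generator with known
    parameters for end-to-end recovery testing, and bootstrap propagation of
    proxy uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    MASS,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
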