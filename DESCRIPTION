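Package: ordtrial
Title: Autoregressive Transitional Ordinal Models and Power Simulation for
    Segmental Motor Score Endpoints
Version: 0.1.0
Authors@R:
    person("ordtrial", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the design and analysis of two-arm randomized trials
    whose endpoint is a multivariate ordinal motor score, such as the Upper
    Extremity Motor Scores (UEMS) used in cervical spinal cord injury.  The
    package implements a cumulative-logit proportional-odds model with an
    autoregressive transitional structure over adjacent spinal segments,
    maximum-likelihood fitting, participant-level permutation inference for
    the treatment effect, a battery of conventional summed-score analyses
    (t-tests, ANCOVA, stratified independence tests) for comparison, a
    trial simulator driven by a reference-population model, and Monte-Carlo
    power-study machinery with Wilson score intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
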