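Package: floquetr
Title: Floquet Multiplier Stability Analysis of Periodically Forced Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the stability of periodically forced, possibly
    spatially extended dynamical systems without prior deseasoning or
    detrending. Estimates Floquet multipliers as eigenvalues of a linear
    propagator fitted by dynamic mode decomposition (DMD) to period-lagged,
    delay-embedded snapshot matrices over sliding windows; tracks, labels
    (seasonal / candidate / noise) and monitors eigenvalue magnitudes for
    stability-threshold crossings, and extracts the spatial modes associated
    with destabilization. Ships seeded stochastic simulators for seasonally
    forced tipping models (pitchfork, logistic, piecewise-noise stationary
    process, a reaction-diffusion vegetation model and a Klausmeier
    pattern-formation model), baseline critical-slowing-down indicators
    (rolling autocorrelation, variance, restoring rate, spatial variance,
    skewness, Moran's I), deseasoning utilities, consensus resampling of
    irregular records, and plain-text I/O plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    e1071,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
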