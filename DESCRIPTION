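Package: nlcc
Title: Nonlinear Population Codes and Choice-Correlation Tests of Decoding Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulators, decoders and statistical tests for nonlinear neural
    population codes, where task information is carried by higher-order
    response statistics (stimulus-dependent variances, covariances and
    third moments) rather than by mean tuning. Provides encoding models
    (XOR, phase- and polarity-nuisance Gabor populations, quadratic and
    cubic exponential-family codes, information-limiting noise), polynomial
    feature construction with residualization, optimal and deliberately
    suboptimal linear-in-features decoders plus a trained feedforward
    network decoder, fine choice correlations and normalized average
    conditional choice correlations (NACCC) with their optimal-decoding
    predictions, decoding-efficiency slopes with bootstrap intervals,
    shuffle controls and null-distribution p-values, and an ideal-observer
    model with synthetic-session generator for a coarse two-alternative
    orientation-variance discrimination task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
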