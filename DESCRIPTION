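Package: loopid
Title: Closed-Loop System Identification of Visuomotor Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Frequency-domain system identification of human visuomotor
    tracking behavior. Designs sum-of-sines reference and disturbance
    stimuli on a prime-multiple frequency grid, simulates closed-loop
    synthetic subjects built from feedforward and feedback pathway
    transfer functions with time delays, estimates closed-loop frequency
    response functions by single-frequency Fourier coefficients, isolates
    the open-loop feedforward and feedback pathways, fits delay and gain
    models (pure gain with delay, first- and second-order lags, the
    McRuer-style leaky integrator) by multi-start Nelder-Mead with
    leave-one-subject-out cross-validation, extracts nonparametric
    preview (lookahead) filters, and computes gain and phase stability
    margins with counterfactual gain-swap simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
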