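Package: timerr
Title: Effects of Timing Measurement Error on Parameter Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and correcting the effects of measurement
    error in the independent variable (most often the time a measurement is
    taken) on parameter inference for models in the biological sciences.
    Provides seeded synthetic-data generators for five case studies (linear,
    oscillator, parasite growth, Gompertz tumour cohorts, GLUT4
    translocation) under classical, Berkson, sequential and biased-uniform
    timing-error mechanisms; naive frequentist fitting with Jacobian-based
    confidence intervals; sequential Monte Carlo Bayesian inference; and
    correction methods including the reliability ratio, Fuller's method of
    moments, regression calibration, orthogonal (Deming) regression, SIMEX,
    and classical/Berkson measurement-error likelihoods, together with a
    rule-based method selector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
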