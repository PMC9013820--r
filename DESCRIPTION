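Package: pathflowsim
Title: Discrete-Event Simulation and Capacity Analysis of a Hospital
    Biopsy Diagnosis Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and simulate the anatomic-pathology biopsy
    diagnosis workflow of a hospital. Provides a seedable Box-Muller
    normal random-variate generator, two-component Gaussian mixture
    service-time models with threshold-based parameter recovery, a
    chain-structured discrete-event simulation engine with resource
    pooling and utilization-based bottleneck detection,
    installed-productive-capacity and full-time-equivalent staffing
    analysis, cost-benefit scenario comparison, a synthetic biopsy-log
    generator for end-to-end testing, and the supporting inferential
    toolkit (chi-square goodness of fit, Anderson-Darling normality
    screening, paired model-validation intervals, and exact
    noncentral-t power and sample-size calculations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
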