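Package: gmixsel
Title: Information-Based Feature-Selection Criteria in Gaussian Mixture
    Generative Tree Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact, quadrature-based information measures for two-component
    equal-weight Gaussian mixtures with shared covariance (differential entropy,
    mutual information with the mixing label, interaction information, total
    correlation), and their use to evaluate the CMI, JMI, CIFE and mRMR
    feature-selection criteria in closed form in a Gaussian generative tree
    model with geometrically decaying class separations. Includes greedy
    forward selection with per-step score traces, crossover diagnostics for the
    JMI and CIFE criteria, the positive-value stopping rule with its positive
    selection rate, a labeled-sample simulator, and Monte Carlo oracles that
    validate the quadrature results.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
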