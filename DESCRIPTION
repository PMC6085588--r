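Package: mmixirt
Title: Multilevel Mixture IRT Modelling of Problem-Solving Process Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-stamped log files from computer-based
    problem-solving assessments with a multilevel mixture item response model.
    Recodes PISA-dialect log events into scored step-by-route response matrices,
    fits a process-level mixture two-parameter logistic (2PL) model with
    class-specific item parameters by an EM algorithm with Gauss-Hermite
    quadrature, scores student-level ability from final-step responses, selects
    the number of latent strategy classes via AIC, BIC, sample-size-adjusted BIC
    and entropy, characterises class-specific route-selection strategies and
    strategy-shift sequences, and relates ability estimates to operational
    variables (clicks, resets, response time). Includes a generative simulator
    that emits synthetic logs in the same dialect for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
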