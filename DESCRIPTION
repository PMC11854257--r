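Package: ivscreen
Title: Interval-Valued Fuzzy Uncertainty Calculus and Federated Screening
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A calculus for epistemic uncertainty on the lattice of closed
    subintervals of the unit interval: four interval comparison regimes
    (componentwise partial order, admissible linear orders, possible and
    necessary relations), order-consistent interval aggregation functions,
    interval-valued precedence and similarity measures, and three families
    of interval entropy (standard, possible, necessary). On top of the
    calculus the package provides an interval k-nearest-neighbour
    classifier for screening-questionnaire records with missing answers,
    entropy-based neighbour selection, an abstention outcome and a
    verification-question override, together with a federated decision
    layer for NON-IID clients (plurality voting with an entropy tie-break
    and an efficiency-gated decision rule) and a synthetic questionnaire
    generator emulating a depression-screening survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
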