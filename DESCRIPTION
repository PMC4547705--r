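Package: mgwnet
Title: Multi-Type Galton-Watson Models of T Cell Proliferation and
    Dissemination on Lymphoid Organ Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time multi-type Galton-Watson branching process with
    migration for generation-structured (CFSE-resolved) lymphocyte
    populations disseminating over a feedforward network of lymphoid
    organs (a draining lymph node source, serial transfer stages, and
    spleen/distal lymph node sinks).  Provides exact first- and
    second-order moment recursions of per-type cell counts, delta-method
    moments of relative cell frequencies, a normal-approximation
    likelihood of observed per-animal frequencies, constrained
    maximum-likelihood estimation of division, quiescence, migration and
    splitting probabilities with Fisher-information standard errors, a
    relative-sensitivity statistic, an exact stochastic path simulator,
    and a generator of synthetic sacrifice-design datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
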