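Package: quantmine
Title: Quantum-Inspired Mining of Higher-Order Associations in Binary Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact classical simulation of small quantum registers applied to
    association mining in patient-by-feature binary tables. Provides amplitude
    encoding of empirical joint distributions, partial traces and entanglement
    entropies as association scores, Grover amplitude amplification over
    combination spaces, estimation and annealing of higher-order (third-order)
    Ising models, a quantum fidelity-kernel support vector machine, a seeded
    synthetic-data generator with planted strictly third-order (parity)
    dependencies, and a deterministic end-to-end pipeline that assembles these
    stages into a ranked gene-symptom-disease association report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
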