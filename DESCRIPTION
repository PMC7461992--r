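Package: cnsot
Title: Power-Equation Risk Model for CNS Oxygen Toxicity at Rest
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the risk of central nervous system oxygen toxicity
    (CNS-OT) for humans at rest breathing hyperbaric oxygen, immersed in
    thermoneutral water or in dry chamber conditions. Implements the
    power-law CNS-OT index K = t^2 * PO2^c with a lognormal (probit-in-log)
    risk transform, exponential recovery of the index during air breaks,
    equivalent-time accumulation across multi-segment exposure profiles,
    linear interpolation of the PO2 exponent over metabolic rate, and
    maximum-likelihood fitting of the underlying lognormal accelerated
    failure time model to right-censored exposure records, with Wald and
    likelihood-ratio tests for immersed versus dry equality. Includes a
    synthetic-record generator, an embedded compilation of historical
    group-level exposure data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
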