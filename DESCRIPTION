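Package: ybsurrogate
Title: Erbium-Filtered Orthovoltage Surrogates of Yb-169 for Gold-Nanoparticle
    Radiosensitization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models an erbium-filtered 250 kVp orthovoltage x-ray beam as an
    external-beam surrogate of the Yb-169 gamma-ray spectrum, scores
    photoelectron and Auger/Coster-Kronig electron release inside a
    gold-nanoparticle-loaded tumor with a desk-scale Monte Carlo photon
    transport, and provides the accompanying radiobiology analysis chain:
    clonogenic survival with linear-quadratic fits and dose-enhancement
    factors, gamma-H2AX focus statistics, gold-uptake comparisons, and
    tumor regrowth-slope inference, together with seeded synthetic-data
    generators for every assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
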