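Package: gppattrib
Title: Attribution of Data-Model Discrepancy in Tropical Forest Gross
    Primary Productivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to decompose the gap between bottom-up biometric
    estimates of forest gross primary productivity (GPP) and
    light-use-efficiency model estimates.  Implements an optimality-based
    photosynthesis model (Farquhar-von Caemmerer-Berry biochemistry with
    least-cost prediction of the ci/ca ratio, Vcmax and Jmax), inversion
    of two-point leaf gas-exchange measurements (Asat, Amax) into
    photosynthetic capacity, carbon-isotope derivation of ci/ca,
    cloud-aware handling of satellite fAPAR series, biometric GPP
    aggregation with error propagation, a factorial experiment engine
    that swaps trait, fAPAR and radiation inputs to attribute the
    data-model discrepancy, and a seeded synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
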