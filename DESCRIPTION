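Package: nmshield
Title: Broad-Beam Radiation Shielding Calculations for Nuclear Medicine
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing photon shielding barriers around
    radiopharmaceutical imaging and therapy rooms (Tc-99m, F-18, I-131 and
    Lu-177, including Lu-177 DOTATATE and PSMA theranostics). Implements the
    three-parameter Archer broad-beam transmission model with published
    fitted parameters for lead, gypsum, concrete, steel and glass, closed-form
    inversion for required barrier thickness, fractional value layers
    (HVL/QVL/TVL/CVL/MVL), a workload/dose-limit/occupancy barrier solver,
    nonlinear fitting of the Archer form to transmission-curve data, and a
    simplified analog Monte Carlo photon transport simulator in the
    source-barrier-tissue slab geometry for generating broad-beam
    transmission and buildup factors.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
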