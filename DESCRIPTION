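Package: vestibulum
Title: Nasal Airway Heat and Water Exchange in Convoluted Vestibules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing heat and water exchange in elongated,
    convoluted nasal airways, motivated by the looping nasal vestibules of
    ankylosaurian dinosaurs.  Provides centerline airway geometry containers
    with transforms (soft-tissue caliber correction, vestibule shortening and
    straightening), a seedable parametric airway generator, Reynolds/Womersley
    flow-regime diagnostics including a reversed-Reynolds maximum-laminar-flow
    estimator, moist-air psychrometrics, respiratory caloric and water budgets
    with allometric tidal volumes, and a reduced-order quasi-1D heat and
    moisture exchanger for desk-scale prediction of axial temperature and
    humidity profiles during inspiration and expiration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
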