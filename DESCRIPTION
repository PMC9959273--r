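Package: chiralloid
Title: DLVO Force-Curve Analysis and Chiral-Nematic Optics for Cellulose
    Nanocrystal Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for charge-regulated chiral self-assembly of
    cellulose nanocrystals (CNCs). Provides a sphere-plate DLVO forward model
    with Debye-parameter, interaction-constant and Lifshitz Hamaker-constant
    calculators; reading, preprocessing and log-linear fitting of colloid-probe
    AFM force-distance curves (kappa, Z, limit distance) with fixed-kappa
    refitting and replicate aggregation; Sauerbrey quantification of QCM-D
    adsorption traces; chiral-nematic pitch and photonic-bandgap relations for
    structural colour; phase-separation critical concentrations and rheological
    gel/liquid-crystal classification; and seeded synthetic-data generators
    emulating each instrument so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
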