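Package: wormdemog
Title: Demographic and Reproductive-Senescence Analysis for C. elegans Lifespan Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetable demography and reproductive-senescence analysis for
    C. elegans RNAi lifespan screens. Builds discrete-day lifetables and
    Kaplan-Meier survival estimates from per-worm event records, fits the
    Gompertz-Makeham mortality model by bounded nonlinear least squares to
    decompose survival effects into initial mortality rate (IMR) and
    demographic rate of aging (RoA), classifies gene inactivations into
    demographic effect groups, scores reproductive lifespan from daily
    progeny schedules with replicate-wise hit calling, and classifies
    pathway epistasis patterns. Includes a seeded synthetic-cohort
    generator so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
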