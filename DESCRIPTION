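Package: hifmir
Title: Kinetic Modelling of MicroRNA Control of the HIF-VEGF Pathway
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-compartment ordinary-differential-equation model of
    hypoxia signalling in endothelial cells, covering oxygen sensing by
    prolyl hydroxylases, HIF-1 stabilisation and nuclear transcription,
    let-7 biogenesis with AGO1-mediated RISC dynamics, and miR-15a
    repression of VEGF.  Provides a generic compartmental reaction-network
    engine (mass-action, Michaelis-Menten and Hill kinetics), a virtual
    experiment layer (hypoxia switching, siRNA silencing, mRNA
    overexpression, miR mimics and antagonists, cobalt chloride),
    steady-state pre-equilibration, Levenberg-Marquardt calibration
    against normalised time-course data, complex-step local sensitivity
    analysis, and in-silico therapy screens for tumour and peripheral
    arterial disease settings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
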