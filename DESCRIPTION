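Package: itieskit
Title: Ion-Transfer Voltammetry Analysis at Electrified Liquid-Liquid Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electroanalytical studies of ionizable drugs at the
    interface between two immiscible electrolyte solutions (ITIES).
    Implements multi-pKa acid-base speciation, ion partition diagram
    modelling and distribution-constant fitting, lipophilicity (logP)
    extraction from formal transfer potentials, Randles-Sevcik diffusion
    coefficient estimation, Saito micro-interface sizing, voltammogram
    signal processing (sweep segmentation, baseline correction, peak and
    steady-state wave extraction, reference-ion potential correction,
    potential-window width and binary presence calls), calibration with
    3-sigma/slope detection limits, standard-addition quantification, and
    a finite-difference simulator of reversible ion-transfer voltammograms
    at macroscopic and microscopic liquid-liquid interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
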