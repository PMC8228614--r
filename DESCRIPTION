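Package: paeqsar
Title: 3D-QSAR Modeling of Phthalate Ester Toxicity
Version: 0.1.0
Authors@R:
    person("PAE", "QSAR Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete 3D quantitative structure-activity relationship
    (3D-QSAR) pipeline for phthalate ester (PAE) toxicity endpoints: rat
    acute oral LD50, 72-hour HepG2 IC50, and relative Nrf2 protein content.
    Provides template-based molecular alignment on the shared phthalate
    diester core, CoMFA (Lennard-Jones steric and Coulomb electrostatic)
    and CoMSIA (Gaussian similarity index) molecular interaction fields
    evaluated on a rectangular grid, partial least squares regression with
    leave-one-out cross-validated q2 and component selection, the Tropsha
    external-validation battery, a leverage-based applicability domain with
    Williams-plot classification, stdev*coefficient contour extraction,
    and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used for SMILES-to-3D embedding, force-field minimization
    and Gasteiger partial charges).
Config/testthat/edition: 3
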