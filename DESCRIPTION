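Package: acinusim
Title: Fluid-Structure Interaction Simulation of Breathing Mechanics in the
    Pulmonary Acinus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of normal and fibrotic breathing mechanics
    in a two-generation pulmonary acinus. Builds a parameterized
    truncated-octahedron (14-hedron) alveolar geometry with primary and
    secondary septa, solves quasi-static Neo-Hookean tissue mechanics on a
    thin-shell discretisation, couples it to incompressible low-Reynolds
    airflow (a Poiseuille duct network by default, a stabilised
    finite-element Stokes solver on tetrahedral meshes for field
    quantities), and extracts lung-function metrics (tidal volume,
    compliance, acinus resistance, pressure-volume and flow-volume loops)
    for healthy, NSIP and IPF septal-thickness scenarios driven by a
    sinusoidal intrapleural pressure waveform.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
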