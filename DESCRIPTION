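Package: tumorphase
Title: Multiphase Continuum Simulation of Tumor Growth with M1/M2
    Macrophage Dynamics and TGF-beta-Targeted Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A finite-volume simulator for a viscous multiphase
    mixture model of tumor growth in healthy tissue.  Seven
    volume-occupying phases (healthy cells, cancer cells, vasculature,
    interstitial fluid, and three macrophage compartments) obey
    coupled mass and creeping-flow momentum balances with inter-phase
    drag, chemotaxis, and a cell-density pressure closure; six
    diffusible species (oxygen, VEGF, CSF-1, CXCL12, EGF, TGF-beta)
    plus an orally dosed TGF-beta-receptor inhibitor are resolved as
    quasi-steady reaction-diffusion fields.  The package solves the
    cancer-free homeostatic equilibrium used for initial conditions,
    advances single- and multi-seed scenarios on a radially symmetric
    disk or a coarse 2-D Cartesian grid, and reports spatial averages,
    radial profiles, tumor radius, and the M2/M1 macrophage ratio,
    including pulsed-dosing immunotherapy schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
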