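Package: rfavein
Title: Axisymmetric Thermo-Fluid Simulation of Endovenous Radiofrequency
    Ablation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Finite-volume simulator for endovenous radiofrequency ablation
    of varicose veins.  Couples quasi-steady incompressible laminar blood
    flow with Carreau-Yasuda shear-thinning rheology to a transient
    conjugate bioheat (advection-diffusion) equation over the vessel lumen
    and wall, heated by a catheter electrode held at constant surface
    temperature and withdrawn at a constant pullback velocity.  Includes
    scenario configuration with unit-aware parsing, structured axisymmetric
    meshing with a blocked-cell moving electrode, post-processing metrics
    (peak interfacial temperature, thermally influenced volume fractions,
    absorbed wall energy), a deterministic scenario-matrix runner with VTK
    and CSV output, and an analytic verification suite (Poiseuille flow,
    semi-infinite conduction, composite-cylinder conduction, manufactured
    solutions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
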