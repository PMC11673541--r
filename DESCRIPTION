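Package: angionet
Title: Hybrid Meshless Simulation of Sprouting Angiogenesis with
    Intravascular Flow and Structural Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates sprouting angiogenesis in a chick chorioallantoic
    membrane (CAM)-like region of interest. A meshless radial point
    interpolation method (RPIM) solves the steady-state VEGF diffusion
    field; agent-based endothelial tip cells migrate up the VEGF gradient
    with stochastic angular perturbation, branch according to an
    order-dependent inter-branch distance law with CAM-calibrated branch
    angles, and anastomose into a capillary graph. Poiseuille flow and
    nodal conservation are solved on the graph by successive
    over-relaxation, and vessel diameters adapt to wall shear stress,
    circumferential (pressure) stress and a metabolic stimulus until the
    network structure converges. Includes patchwise capillary
    volume-fraction quantification, branch-angle statistics, stress
    summaries, file import/export and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
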