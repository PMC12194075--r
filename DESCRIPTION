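Package: morphocell
Title: 3D Deformable-Cell Simulation of Epithelial Sheet Bending
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-dimensional deformable-cell vertex model for studying
    epithelial morphogenesis, in particular apical constriction and the
    invagination of an endodermal plate into a hollow blastula. Each cell is
    a closed triangulated cortex of nonlinear elastic edges around a
    conserved volume; cells interact through stochastic constant-force
    adhesion bonds and vertex-triangle collision handling, and the system is
    integrated with a damped Verlet scheme. Scene builders assemble single
    cells, detached hexagonal plates, planar rings between confining plates,
    and hollow blastulas with typed cells and timed constriction or stiffness
    schedules; measurement utilities quantify cell elongation, apical
    extents, invagination depth and blastoporal opening, and snapshots can be
    exported as Wavefront OBJ or legacy VTK with a bond table alongside.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
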