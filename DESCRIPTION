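Package: stokescell
Title: Fluid-Structure Simulation of Single-Cell Migration Through a
    Deformable Extracellular Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-dimensional cross-section of a single cell
    migrating through a fibrous extracellular matrix (ECM).  The cell is
    modelled as two closed elastic contours (actomyosin cortex and nucleus)
    immersed in Stokes flow, the ECM as a random node-and-spring lattice,
    and all structures are advected with the fluid velocity obtained by the
    method of regularized Stokeslets.  Two event-driven motility mechanisms
    are implemented: a mesenchymal-like push-pull cycle (one protrusion
    binds one ECM node and global cortical stiffening pulls the cell body
    forward) and an amoeboid-like rear-squeezing cycle (two protrusions
    bind two adjacent nodes and the rear arc of the cortex contracts,
    squeezing the nucleus through the gap).  The package provides lattice
    generation, the elastic force models, the motility state machines,
    equal-arclength remeshing, migration metrics (nuclear displacement,
    aspect ratio, penetration fraction), pressure/velocity field maps, and
    named parameter presets for the tension/ECM/nucleus force-ordering
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
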