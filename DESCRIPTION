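Package: iknm
Title: Individual-Based Simulation of Interkinetic Nuclear Migration in a
    Growing Pseudostratified Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interkinetic nuclear migration (IKNM) in a growing
    pseudostratified epithelium such as the Drosophila wing imaginal disc.
    Nuclei are deformable convex 20-sided polygons confined in a 2D elastic
    box and advanced by constrained energy minimization (an implicit-Euler
    gradient flow over nuclear vertices, cable anchors and box degrees of
    freedom), coupled to a cell-cycle state machine with an apical mitotic
    gate and an optional basal S-entry gate of range lambda. Provides
    ensemble drivers, trajectory and event recording, and the summary
    statistics used to characterise nuclear crowding: phase censuses,
    apical-basal distributions, crowding indices, G2 durations and arrests,
    terminal pre-mitotic velocities, and tissue layering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
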