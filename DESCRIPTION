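Package: bioprintCA
Title: Cellular-Automaton Simulation of Post-Printing Cell Dynamics in
    Bioprinted Hydrogel Scaffolds
Version: 0.1.0
Authors@R:
    person("bioprintCA", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 3D lattice cellular-automaton model of tumour-cell behaviour
    inside a porous bioprinted gelatin/alginate scaffold. Cells carry
    stochastic doubling times, divide into vacant Moore-neighbourhood sites
    under a carrying-capacity rule, enter quiescence when space or capacity
    runs out, die after prolonged quiescence, and perform random or biased
    random-walk movement attracted to neighbouring cells and scaffold pores.
    Includes ensemble Monte-Carlo drivers, derived metrics (fold
    proliferation, viability, Ki-67-like proliferating fraction, voxel
    cluster statistics, consistency analysis), weighted-least-squares
    calibration of free parameters to packaged in-vitro time courses,
    validation scenarios, and a command-line interface with CSV/JSON/TIFF
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
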