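Package: pottsgrowth
Title: Cellular Potts Simulation of Tissue Growth and Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-layer cell-based simulator of growing epithelial tissues.
    The physical layer is a Cellular Potts Model (lattice sites carrying cell
    identities, interfacial contact energies and an area-elastic energy,
    evolved by Metropolis-Hastings copy dynamics). The decision layer applies
    cell-autonomous rules once per Monte Carlo step: crowding-suppressed
    growth of the target area, a G1 sizer / S-G2-M timer cell cycle with
    division along the plane perpendicular to the cell's long axis,
    density-dependent apoptosis and live-cell extrusion. A companion
    zero-dimensional continuum model describes whole-colony growth under
    confinement. Observables include colony growth time, homeostatic density,
    birth and elimination rates, radial cell-area profiles, cell-cycle
    statistics, pressure gradients at the colony boundary and G1-arrest
    fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
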