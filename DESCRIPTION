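Package: softcapsid
Title: Coarse-Grained Molecular Dynamics of Deformable Viral Capsomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator for the self-assembly of T=1 icosahedral virus
    capsids from deformable trapezoidal capsomers. Each capsomer is a
    78-bead elastic network (harmonic stretching edges plus dihedral
    bending edges) with short-range attractive interaction sites embedded
    in its lateral walls; capsomer-capsomer sterics use truncated and
    shifted Lennard-Jones potentials and an optional screened (Yukawa)
    electrostatic term for charged capsomers. Dynamics are propagated by
    velocity Verlet in the NVT ensemble with a Nose-Hoover chain
    thermostat (NVE and damped-quench modes are available for
    validation), accelerated by a capsomer-as-mobile-cell Verlet neighbor
    list. Analysis tools provide cluster-size statistics (Nmax, Nav),
    assembly-state classification, edge-length and bending-angle
    fluctuation measures, and per-face binding energies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
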