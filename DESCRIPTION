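Package: aggrex
Title: Geometry, Exciton and Embedded-Cluster Analysis for Molecular Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying excited states of molecular crystals and
    clusters: unit-cell manipulation (supercells, molecule completion,
    spherical cluster extraction), grid-based Voronoi packing volumes with a
    van der Waals scaled metric, dimer enumeration and fingerprint
    deduplication with principal-axis and slip-angle descriptors, exciton
    classification from Mulliken fragment densities, exciton couplings by
    point-dipole, atomic-transition-charge, half-gap and N-state
    diabatization schemes, Ewald lattice potentials with constrained
    point-charge fitting, connectivity-fingerprint charge redistribution,
    and subtractive ONIOM QM:QM' energies, gradients and optimizations
    (minima and minimal-energy conical intersections via a penalty
    function), all driven through an abstract calculator contract so that
    every component can run against analytic model potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
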