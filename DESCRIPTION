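Package: ljphase
Title: Binodal and Spinodal Lines of Lennard-Jones Fluids from Molecular
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates both the binodal (coexistence) and spinodal lines of a
    van der Waals fluid -- monomeric Lennard-Jones particles and coarse-grained
    bead-spring chains -- directly from molecular-dynamics trajectories,
    without requiring an equation of state.  Includes a reduced-unit NVE/NVT
    simulation engine (velocity Verlet, Nose-Hoover chain thermostat,
    truncated Lennard-Jones plus harmonic bonds), contact-based cluster
    analysis under periodic boundaries, bin-occupancy statistics for the
    liquid binodal branch, cluster-growth detectors for the vapor binodal and
    liquid spinodal branches, specific-heat anomaly detection for the
    spinodal, a fluctuation-based surface-tension estimator, and a state-point
    scanner that assembles phase diagrams and estimates the critical point.
    Reads and writes extended XYZ and LAMMPS-style text dump trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
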