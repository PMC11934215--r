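Package: groovedyn
Title: Trajectory Analysis of Allosteric Groove Opening in Helical Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect how distal contacts gate the opening of a
    protein binding groove from molecular dynamics trajectories, built
    around the 14-3-3 amphipathic-groove problem. Provides structure and
    trajectory input (PDB, multi-model PDB, DCD), atom selections,
    Kabsch superposition, RMSD/RMSF and inter-atom distance series with
    histogram peak detection, displacement-correlation residue networks
    with contact-persistence gating and Dijkstra shortest-path maps,
    lagged cross-correlation of distance time series with event
    ordering, essential-dynamics PCA with cosine-content convergence
    diagnostics, and free-energy landscapes by Boltzmann inversion of
    principal-component histograms. Includes generators for synthetic
    trajectories with known covariance, two-state opening kinetics and
    injected lead-lag couplings, so every analysis stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    MASS,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
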