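Package: memscan
Title: Membrane Insertion, Interaction Energetics and Active-Site Geometry
    of Peripheral Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    protein-membrane-ligand systems, aimed at peripheral membrane enzymes
    such as carotenoid cleavage dioxygenases.  Implements membrane
    penetration geometry from phosphate leaflet sets (bilayer thickness,
    protein penetration depth and relative penetration depth), per-residue
    RMSF and membrane-versus-solvent fluctuation contrasts, a 12-6
    Lennard-Jones plus Coulomb interaction-energy partition, MM/PBSA
    binding free energies with an in-package finite-difference linearized
    Poisson-Boltzmann solver and Shrake-Rupley solvent-accessible surface
    areas, protein-membrane contact surfaces and hydrogen-bond series,
    carotenoid carbon-to-iron distance profiling with cleavage-site
    assignment, and a rigid-body implicit-slab insertion optimizer.  A
    synthetic-system generator produces bilayer, protein and ligand models
    with known ground truth so the full pipeline is testable without any
    simulation engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
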