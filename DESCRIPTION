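Package: hybridff
Title: Hybrid Machine-Learned Force Field with Universal Long-Range Physics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-term decomposition of the molecular potential energy that couples a
    semilocal message-passing atomic-property model with universal physically motivated
    pairwise interactions: Ziegler-Biersack-Littmark screened nuclear repulsion,
    erf-damped point-charge electrostatics, and a quantum-Drude-oscillator dispersion
    series parametrized from environment-scaled (Tkatchenko-Scheffler) polarizabilities.
    Includes analytic forces through all parameter couplings, joint force/dipole/Hirshfeld
    training of the model readouts, damping-hyperparameter calibration on dimer scans,
    an NVE/NVT/NPT molecular-dynamics engine, trajectory observables (radial distribution
    functions, self-diffusion, Ramachandran free-energy surfaces, lagged RMSD, vibrational
    power spectra, lipid order parameters and bilayer metrics), atom-environment orbit
    counting for chemical-space coverage analysis, and deterministic synthetic-structure
    generators. Structures are read and written as extended XYZ; PDB is read for
    biomolecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
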