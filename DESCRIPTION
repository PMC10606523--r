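Package: ContinuumPKa
Title: Continuum-Electrostatics pKa Calculations for Membrane Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pKa values of protonatable residues in membrane proteins
    with a semi-continuum dielectric model: a heterogeneous four-layer protein
    dielectric derived from the local density of polar side-chain atoms, an
    implicit membrane slab with distinct acyl-core and headgroup permittivities,
    a finite-difference linearized Poisson-Boltzmann solver for Born-type
    dielectric response, background-field and site-site interaction energies,
    and multi-site protonation sampling by exact enumeration or Metropolis
    Monte Carlo. Includes trajectory-ensemble error analysis, sequence-level
    residue censuses, and synthetic fixture generators with analytic ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
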