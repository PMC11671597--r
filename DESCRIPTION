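Package: dartsdeconv
Title: DARTS-LC-MS/MS Drug Target Deconvolution and Binding Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for label-free drug target deconvolution
    by drug affinity responsive target stability (DARTS) coupled to
    LC-MS/MS peptide evidence. Simulates three-condition partial-proteolysis
    experiments over a mock proteome with a dose-dependently protected
    ligand-binding footprint, maps peptide evidence to protein sequence
    coverage, screens candidate targets through a degradation/stabilization
    filter cascade with fold-change ranking, estimates binding parameters
    by four-parameter-logistic EC50 and 1:1 quadratic-isotherm Kd fits with
    bootstrap uncertainty, computes ensemble alanine-scanning interaction
    energies (Coulomb with distance-dependent dielectric plus 12-6
    Lennard-Jones) with per-residue delta-delta-G hotspot tiers, and
    provides deterministic molecular-dynamics system bookkeeping (ion
    counts, leaflet composition, snapshot schedules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    bio3d,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
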