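Package: alsite
Title: Template-Free Modelling of Pre-Organized Al(III) Binding Sites in
    Amyloid-Beta Peptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects pre-organized octahedral Al(III) binding sites in
    multi-conformer (NMR-style) peptide structure ensembles and builds 3D
    metallopeptide models without a structural template.  A grid protocol
    screens each conformer for loci surrounded by carboxylate-rich donor
    side chains, a multi-objective genetic algorithm (non-dominated
    sorting with crowding) refines the metal position and donor chi
    angles against clash-volume, donor-distance and octahedral-geometry
    objectives, and surviving solutions are completed to coordination
    number six with explicit water oxygens.  Ships curated reference
    tables of quantum-cluster interaction energies and final-complex
    first-shell descriptors for the Al(III)-amyloid-beta system, and a
    synthetic-fixture generator that plants ground-truth octahedral
    O-donor sites for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
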