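Package: scaffrelax
Title: Restrained All-Atom Relaxation and Design Evaluation for Protein
    Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Prepares protein structures for computational design by
    relieving energetic strain while staying close to the input
    coordinates.  Implements harmonic and bounded coordinate restraints
    and sidechain-sidechain distance restraints, a cyclic
    repack-and-minimize relaxation protocol with repulsive-weight ramping,
    Kabsch superposition RMSD, replicate aggregation with Pareto-front
    analysis of the energy/RMSD trade-off, and fixed-backbone sequence
    design with shell detection and sequence-recovery scoring.  A
    deterministic generator of ideal-geometry mini-proteins with planted
    clashes and rotamer strain supports testing without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
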