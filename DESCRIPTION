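Package: subalign
Title: Suboptimal Sequence Alignment Ensembles Guided by Template Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates ensembles of alternative (suboptimal) pairwise
    sequence alignments for template-based protein structure modeling.
    Instead of perturbing a dynamic-programming optimum, the sampler
    aligns the query to short ungapped fragments inside the template's
    secondary structure elements, enumerates mutually consistent fragment
    combinations, discards combinations that could not produce a plausible
    three-dimensional model (loop stretch, contact order, beta-sheet
    pairing, preserved hydrophobic core contacts, distance-dependent
    statistical energies), and finishes each survivor into a full
    alignment with corridor-restricted dynamic programming.  Also provides
    classical delta-suboptimal Waterman ensembles (unconstrained and
    secondary-structure-constrained), alignment-shift metrics (IAD, FDS2),
    ensemble diversity statistics, a trainable distance-dependent
    statistical potential, and a deterministic generator of idealized
    template folds and derived remote-homolog queries for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
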