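Package: helixforge
Title: Multi-Template Homology Modeling of G Protein-Coupled Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative modeling of
    G protein-coupled receptors (GPCRs) from low-identity templates.
    Builds blended sequence/structure multiple alignments of template
    structures anchored on Ballesteros-Weinstein x.50 residues, aligns
    structure-less targets into them with knowledge-based loop rules,
    ranks and filters templates by pairwise sequence identity, threads
    targets onto template backbones, recombines multiple partial threads
    by Monte Carlo segment swapping and fragment insertion under a
    lightweight composite score, and evaluates models with region-specific
    RMSD statistics. Includes a generator of idealized seven-transmembrane
    receptor families with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
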