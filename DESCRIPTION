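Package: fodm
Title: Fuzzy Oil Drop Analysis of Hydrophobicity Distributions in Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how closely the hydrophobicity distribution of a
    protein structure (or amyloid fibril assembly) matches an idealized
    micelle-like organization. Fits a 3D Gaussian envelope to a structural
    unit, computes theoretical (T), observed (O, Levitt pairwise function)
    and uniform reference (R) per-residue hydrophobicity profiles, the RD
    statistic based on Kullback-Leibler divergence, and the environment
    modification parameter K of the modified (M) field. Supports chain,
    proto-fibril and super-fibril structural units from PDB/mmCIF files,
    stepwise residue elimination to locate micelle-like cores, seeded
    synthetic fixtures, batch catalogs and profile plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
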