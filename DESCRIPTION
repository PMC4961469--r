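Package: alpscan
Title: Lipid Packing Defect Scanning and Amphipathic Helix Analysis for
    ALPS-Motif Curvature Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studying how amphipathic
    lipid-packing sensor (ALPS) motifs such as the N-terminal helix of the
    golgin GMAP-210 read membrane curvature and lipid packing. Generates
    coarse-grained bead-model bilayers (flat patches, tubules, vesicles)
    with controllable composition and ground-truth voids, scans their
    interfacial surface for lipid packing defects, fits the exponential
    defect-area distribution e^(-A/Ac) and curved/flat enrichment ratios,
    analyses amphipathic helix sequences (hydrophobic moment, helical
    turn partitioning, sparse versus paired hydrophobic spacing,
    inversion, condensation and point mutations), converts Golgi-region
    fluorescence into captured-liposome counts, and quantifies synthetic
    two-channel micrographs (marker masks, Golgi/cytosol ratios, Pearson
    colocalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    bio3d,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
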