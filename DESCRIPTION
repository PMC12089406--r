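Package: nacsel
Title: Near-Attack-Conformation Analysis and C-H Site-Selectivity
    Classification for Fe(IV)-oxo Dioxygenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how non-heme Fe(II)/alpha-ketoglutarate
    dependent dioxygenases choose among chemically similar aliphatic C-H
    bonds.  Reads multi-model coordinate ensembles (PDB/mmCIF), perceives
    covalent topology and candidate CH/CH2/CH3 sites on diketopiperazine
    substrates, places ideal-geometry hydrogens, counts near-attack
    conformations (ferryl O...H distance and O-H-C angle criterion) over
    conformer ensembles, ranks sites by inherent reactivity from a
    hydrogen-abstraction barrier table, detects directing-group hydrogen
    bonds, estimates active-site pocket volumes on a grid, and classifies
    each enzyme's site-selectivity strategy as substrate innate control,
    steric hindrance control, or directing-group control.  Includes a
    synthetic active-site and ensemble generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
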