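Package: pocketmap
Title: Inferring Receptor-Peptide Binding Pockets from Comparative Genomics
    and Predicted Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for locating the ligand-binding pockets of
    leucine-rich-repeat receptor kinases (LRR-RKs) that perceive short
    secreted signaling peptides.  Candidate peptide precursors and receptor
    homologues are mined from multi-species gene tables by synteny-anchored
    locus comparison, clustered and scanned with position-specific scoring
    profiles, and curated by LRR repeat architecture.  Conservation across
    validated homologues is projected onto a repeat-by-position grid
    (repeat conservation mapping), predicted receptor-peptide complexes are
    filtered by interface confidence (ipTM) and reduced to consensus
    hydrogen-bond pockets, and the overlap between predicted contacts and
    conserved surface patches is quantified with a permutation test.  A
    seeded synthetic-data generator emulates every input so the whole
    pipeline is testable without external genomes or structure predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
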