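Package: mastkit
Title: Metagenomic Amplicon Strain Typing of Host-Associated Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strain-level analysis of deep-sequenced amplicon
    marker genes (metagenomic amplicon strain typing, MAST). Calls strains
    as exact full-length amplicon haplotypes from quality-filtered merged
    reads, builds strain and host co-occurrence matrices from a
    Sorensen-Dice score, groups strains into co-occurrence clusters with
    Markov clustering (MCL), and provides the accompanying permutation
    machinery: geography randomization, strain-reassortment nulls,
    interspecies association tests and saturation (accumulation) curves.
    Includes a synthetic-data generator with planted strain clusters and
    known ground truth, codon-position-aware sequence-evolution
    simulations for testing PCR-artifact and purifying-selection
    explanations of shared haplotypes, and a cryptic-strain rescue that
    relaxes the calling threshold to single-read support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
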