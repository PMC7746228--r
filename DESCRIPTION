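Package: grlscreen
Title: Screening and Assessment of Candidate Gustatory Receptor-Like Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for screening candidate Gustatory
    Receptor-Like (GRL) proteins in unicellular eukaryotes. Predicts
    transmembrane topology from hydropathy with positive-inside orientation,
    applies the five GRL retention criteria (reciprocal-hit family check,
    length band, seven transmembrane domains, intracellular N-terminus,
    intracellular-over-extracellular loop balance), scans TM7 for the
    diagnostic (T/S)Yhhhhh(Q/K/E)(F/L/M) motif with conservative-substitution
    accounting, builds pseudocounted sequence profiles and all-vs-all
    similarity matrices, computes pairwise identities, progressive multiple
    alignments and neighbor-joining trees, maps intron positions onto protein
    and alignment coordinates, and compares coordinate models by Kabsch
    superposition, RMSD and TM-score with fold-classification thresholds.
    Seeded synthetic-data generators emit every input class with planted
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
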