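Package: xerscan
Title: Prediction of Xer Recombination (dif) Sites and Replication-Polarized
    Sequence Skews in Circular Prokaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for locating chromosome-dimer
    resolution (dif) sites and replication-oriented short polarized sequences
    (KOPS/ASPS) on circular prokaryotic chromosomes. Enumerates imperfect
    inverted repeats in intergenic DNA, filters candidates by cross-genome
    conservation, summarises conserved groups as IUPAC consensus sequences
    with per-column information content, extends predictions to new genomes
    with a positional log-odds profile calibrated against a
    dinucleotide-preserving shuffled null, detects strand-polarized words by
    maximal-order Markov over-representation under a rotating replication
    terminus, and localises predictions in origin-relative angular
    coordinates. Includes a synthetic-genome simulator with planted sites and
    polarized words so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
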