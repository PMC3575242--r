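Package: temosaic
Title: Recombination Mosaic Analysis for Transposable-Element Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises inter-allelic recombination in
    alignments of transposable-element sequences, such as Pokey elements
    inserted in Daphnia ribosomal DNA. Provides alignment preparation
    (ambiguous/indel column stripping with coordinate maps, partitions,
    translation), nucleotide diversity statistics (pi, Watterson's theta,
    per-partition summaries, the population recombination rate 4Nec),
    recombination inference (pairwise homoplasy index test, stepwise
    maximum chi-square breakpoint detection with Monte Carlo permutation
    significance, Hudson-Kaplan Rm, a combined haplotype lower bound Rh,
    and an exhaustive two-breakpoint incongruence scan), neighbor-joining
    dendrograms per recombination fragment with parental-donor assignment,
    in-silico PCR-RFLP haplotyping, and a fully seeded mosaic-sequence
    simulator with ground-truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
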