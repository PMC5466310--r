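Package: mitocharr
Title: Comparative Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the desk-scale comparative characterization of
    animal (especially lepidopteran) mitochondrial genomes. Provides a
    data model for circular annotated mitogenomes with readers and
    writers for annotation tables, FASTA and GenBank flat files;
    per-region base composition and AT/GC strand-skew statistics;
    codon usage, relative synonymous codon usage (RSCU) and start/stop
    codon classification under the invertebrate mitochondrial genetic
    code, including incomplete stop codons completed by polyadenylation;
    accounting of gene overlaps and intergenic spacers on the circle;
    scanning of the A+T-rich control region for conserved motifs,
    homopolymer stretches, microsatellites and perfect tandem repeats;
    gene-order comparison by breakpoint counting; neighbor-joining
    phylogeny of concatenated protein-coding genes with bootstrap
    support; and a seeded synthetic-mitogenome generator so that every
    analysis stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
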