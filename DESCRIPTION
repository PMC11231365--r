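Package: strandhap
Title: Chromosome-Scale Haplotype Phasing from Single-Cell Strand-Specific Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing single-cell, strand-specific long-read
    (Strand-seq style Nanopore) libraries: demultiplexing of combinatorially
    barcoded reads by Levenshtein distance, linker trimming and chimera
    removal, alignment filtering and PCR duplicate marking with edge
    tolerance, per-cell strand-state quality control, detection of putative
    inversions from directional composite read sets, two-round reconstruction
    of whole-chromosome scale haplotypes with consensus SNP calling,
    haplotype genotyping and phasing of structural variants, and strand-based
    clustering of de novo assembly contigs into chromosome-scale groups.
    Includes a truth-annotated simulator of diploid genomes and single-cell
    directional read libraries so that every stage can be exercised and
    evaluated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
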