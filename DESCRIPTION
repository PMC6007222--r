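Package: orthomark
Title: Comparative Synteny Analysis and SNP Marker Discovery for Closely
    Related Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate orthologous genes between closely related
    genomes and links them to SNP markers ready for primer design. Genes are
    grouped into homolog clusters by greedy incremental clustering at a
    sequence-identity cutoff, cross-genome ortholog anchors are chained into
    collinear synteny blocks under quality filters (e-value, identity,
    coverage), every gene is classified by homology status relative to a
    derived chromosome pairing, and target genes are connected to minor-allele-
    frequency-filtered SNPs with flanking sequences in bracket notation. A
    synthetic-data module plants homology, rearrangements, divergence and
    allele frequencies so the whole pipeline is testable without external
    downloads; static SVG views export whole-genome, chromosome-comparison and
    synteny-block summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
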