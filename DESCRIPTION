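Package: cazomer
Title: Consensus CAZyme Annotation and Carbohydrate Gene-Cluster Screens
    for Holobiont Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the carbohydrate-active enzyme repertoire
    (CAZome) of a host and its associated microbiota from assembled
    metagenome and transcriptome annotations. Implements conservative
    three-tool consensus CAZyme calling from HMM-domain, sequence-similarity
    and peptide-signature evidence; module counting and library-size
    normalization of family abundances; classification of calls into
    lignocellulose functional classes (cellulases, hemicellulases,
    lignin-modifying enzymes) with activity-prediction override; naive
    lowest-common-ancestor taxonomic attribution of CAZyme-encoding ORFs;
    and gene-cluster screens on contigs for polysaccharide utilization loci
    (sequential susC-susD pairs) and cellulosomes (cohesin, dockerin and
    S-layer homology domains co-located with CAZymes). A synthetic-data
    generator plants loci with known ground truth so every stage is
    testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
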