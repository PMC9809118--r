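Package: dinomfrs
Title: Discovery of Novel MHC Class I Alleles from RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotyping of highly polymorphic, multi-copy MHC class I genes
    from paired-end RNA-Seq reads by iteratively combining alignment against a
    curated exon2-exon3 allele reference database with stringent de novo
    reassembly of candidate read subsets. Provides the reference-database
    builder with redundancy filtering, a seed-and-extend banded paired-end
    read mapper with discovery and verification scoring regimes, pileup-based
    allele calling with expression binning, a greedy overlap-layout-consensus
    micro-assembler, the iterative per-individual discovery loop with
    reference augmentation, allele annotation (closest known allele,
    translation, antigen-contact classification, gene-conversion screening,
    diversity statistics), exon-wise matching of alleles to genomic contigs,
    and a fully seeded synthetic-data generator with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
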