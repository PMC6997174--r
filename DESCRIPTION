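Package: corephylo
Title: Whole-Genome Core-SNP Phylogeny from Assemblies and Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained workflow for whole-genome single-nucleotide
    polymorphism (SNP) phylogenetics across complete genomes, draft
    assemblies and raw sequencing reads. A reference genome is chosen
    automatically by MinHash sketch distance, repeats are masked by
    self-comparison, assemblies are aligned to the reference with a
    maximal-unique-match anchor aligner, reads are placed with a
    unique-best seed-and-extend mapper and called by pileup consensus
    under depth and allele-fraction thresholds. Per-sample calls are
    fused into an allele table from which the core genome, core-SNP
    alignments and pairwise SNP matrices are derived, supporting subset
    re-analysis and incremental sample placement without realignment.
    Trees are inferred by neighbor joining on per-site distances with
    bootstrap supports, SNPs are partitioned by annotation into coding
    and intergenic classes, and genes are screened for selection with a
    Nei-Gojobori counting dN/dS test. A sequence-evolution simulator
    with planted ground truth backs the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
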