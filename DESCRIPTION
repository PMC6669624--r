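Package: isovar
Title: Comparative Variant Analysis of Closely Related Viral Isolate Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterising a novel virus isolate against a panel of
    related, fully sequenced isolates. Scans a whole-genome multiple alignment
    for single-nucleotide polymorphism (SNP) columns under a strict no-indel
    filter, attributes per-isolate uniqueness, and lifts coordinates between
    isolate frames; annotates coding effects of substitutions and indels on
    open reading frames (truncation, extension, fusion, split, absence); calls
    intra-isolate single-nucleotide variants (SNVs) from read pileups with a
    minimum variant-frequency rule; cross-references SNVs with inter-isolate
    SNPs to quantify genotype-mixture evidence; and builds a distance-based
    phylogeny (neighbor joining with minimum-evolution refinement and
    bootstrap) annotated with per-branch SNP counts. A synthetic cohort
    simulator with a complete truth ledger lets every stage run and be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
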