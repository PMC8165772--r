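Package: sweepscan
Title: Selective-Sweep Scans and Population-Genomic Statistics for
    Two-Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting domestication-style selective sweeps from
    multi-sample SNP data. Reads and filters multi-sample VCFs into genotype
    matrices, annotates SNPs against gene models (synonymous/nonsynonymous
    calls included), computes sliding-window nucleotide diversity, Watterson's
    theta, Tajima's D and FST (Weir-Cockerham or Hudson), scans for joint
    FST / log2 diversity-ratio outlier windows and merges them into candidate
    selected regions, summarizes linkage-disequilibrium decay from genotype
    dosages, and builds individual-level p-distance neighbor-joining trees
    with SNP-resampling bootstrap support. A structured-coalescent simulator
    with infinite-sites mutation and planted sweep regions generates fully
    specified synthetic datasets (VCF, population map, reference FASTA, gene
    models, per-window truth) so every stage of the pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
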