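Package: pedcurate
Title: Pedigree-Based Curation of SNP Array Genotypes for Clonally
    Propagated Diploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation workflow for genome-wide SNP genotypic data of
    pedigreed, outbreeding, clonally propagated diploid crops such as
    apple, peach, and sweet cherry. Implements sample quality and ploidy
    screening from B-allele frequencies, reliability filtering of SNPs
    from call statistics, duplicate detection by pairwise genotype
    identity, verification and reconstruction of pedigree records from
    parent-child and parent-parent-child Mendelian-inconsistent error
    counts, pedigree-wide Mendelian consistency checking by genotype
    elimination with forced imputation, deterministic pedigree phasing
    with double-recombination and singleton diagnostics, map-order
    evaluation by graphical genotyping, haploblock construction with
    integer-coded haplotypes, and a seven-type SNP classification
    ledger. A simulator generates multi-generation pedigrees with
    map-based recombination and injected error scenarios so that every
    stage is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
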