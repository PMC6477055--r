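Package: famphase
Title: Family-Based Haplotype Phasing and Dosage Correction for Polyploid F1 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Read-based haplotype estimation for autopolyploid F1 populations
    consisting of two parents and their full-sib offspring. Parental haplotypes
    are estimated over read-connected SNP blocks by greedy Bayesian SNP-by-SNP
    extension with branching and pruning, pooling the sequence reads of the
    whole population; offspring haplotypes are then selected from the Mendelian
    transmissions of the parental haplotypes by the minimum error correction
    (MEC) criterion. Erroneous or missing allele dosages are corrected and
    imputed from parent-offspring relationships under random polysomic
    segregation. Includes a paired-end F1 read simulator, haplotype evaluation
    metrics (reconstruction rate, pairwise phasing accuracy, SNP missing rate,
    incorrect dosage rate, phasing gaps per SNP, nucleotide diversity),
    haplotype-tagging SNP selection, and a benchmark driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    optparse,
    Rsamtools,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
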