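Package: paraconv
Title: Gene Conversion and Divergence Analysis for Duplicated Genes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular-evolution toolkit for pairs of duplicated genes
    sequenced as haplotypes across multiple populations. Implements
    polymorphism and divergence statistics (nucleotide diversity by site
    class, segregating sites, Tajima's D, Nei-Gojobori Ka/Ks with
    Jukes-Cantor correction, sliding-window Dxy, Shannon entropy), a
    permutation-based gene-conversion scan with population by paralog group
    structure in the style of Sawyer's statistic, conversion signatures
    (shared-paralog sites, haplotype classing, chimeric-haplotype donor
    profiling with breakpoint calls), partitioned Fitch parsimony
    phylogenetics with bootstrap and majority-rule consensus, and a forward
    simulator of duplicate-gene evolution with known conversion tracts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
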