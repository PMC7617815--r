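Package: sexchromr
Title: Sex-Chromosome Recombination Landscapes, Y-Gametolog Reconstruction
    and Gametolog Divergence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing young plant sex chromosomes from genetic
    maps, pedigree sequencing and expression data. Anchors genetic-map
    markers to a genome assembly, builds sex-specific Marey maps with
    isotonic smoothing, estimates windowed recombination rates and segments
    chromosomes into distal recombining and pericentromeric rarely
    recombining regions. Reconstructs Y-linked gametolog coding sequences
    from segregation of father-to-son diagnostic SNPs in a two-generation
    cross, estimates synonymous and nonsynonymous divergence with a
    pathway-averaged Nei-Gojobori estimator and additive three-taxon branch
    decomposition, summarises allele-specific expression bias, and scans
    genomes for gene and transposable-element density. A forward simulator
    of gametolog triplets, sequenced crosses, genetic maps and expression
    counts provides ground truth for parameter-recovery testing of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Software, SNP, Sequencing, GeneExpression
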