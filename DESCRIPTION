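Package: paleosyn
Title: Synteny Blocks, Paleopolyploidy and Silent-Site Clocks from Ordered
    Marker Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls synteny blocks between an ordered physical (or genetic)
    marker map of a query genome and the annotated pseudomolecules of subject
    genomes, quantifies synteny erosion, detects whole-genome duplications
    from the ratio of secondary to primary parallel block lengths and from
    intra-genome block duplication, pairs homoeologous chromosomes and
    reconstructs ancestral chromosome composition, profiles recombination
    rates along chromosomes to localize centromeres, and estimates silent-site
    substitution rates from syntelog pairs with the Nei-Gojobori method. A
    genome-evolution simulator (whole-genome duplication, dysploid fusion,
    inversion, translocation, transposition, gene loss, centromere-suppressed
    recombination, silent-site divergence) provides ground-truthed inputs for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    optparse
Config/testthat/edition: 3
biocViews: ComparativeGenomics, WholeGenomeDuplication, Genetics, Software
RoxygenNote: 7.3.3
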