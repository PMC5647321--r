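Package: paleoploid
Title: Dating Polyploidization Events from Four-Fold Degenerate Transversion Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for dating whole-genome duplication
    (polyploidization) and speciation events from the transversion rate at
    four-fold degenerate codon sites (4dTv) of paralogous and orthologous gene
    pairs. Includes a codon-aware pairwise aligner and 4dTv calculator, a
    dynamic-programming collinear anchor chainer that assembles syntenic
    blocks, kernel-density peak detection with a two-lineage molecular clock
    that converts 4dTv peaks to divergence times in million years, gene-family
    statistics (hypergeometric domain enrichment, expansion profiles from
    amino-acid p-distances, qPCR delta-delta-Ct fold changes), and a
    Kimura-two-parameter allopolyploid genome simulator that generates CDS
    FASTA, GFF3, homology hits and ground-truth divergence tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
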