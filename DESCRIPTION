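Package: mitochar
Title: Characterization and Distance Phylogenetics of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing annotated circular mitochondrial
    genomes and for distance-based phylogenetics. Given a gene table or
    GenBank flat file the package computes gene-map analytics (junction
    gaps, overlaps, intergenic spacers), partitioned base composition with
    AT/GC strand skews, codon usage under the vertebrate mitochondrial
    genetic code (start/stop classification including incomplete stop
    codons, RSCU, codons per thousand codons), and cross-genome start/stop
    and composition matrices. Given a pre-aligned set of mitogenomes it
    computes Kimura 2-parameter distances, builds neighbor-joining trees
    and nonparametric bootstrap supports, and writes Newick. Deterministic
    generators for self-consistent synthetic mitogenomes and simulated
    alignments make every analysis testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
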