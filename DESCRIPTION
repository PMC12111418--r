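Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing annotated circular mitochondrial
    genomes of vertebrates, in particular teleost fish. Derives gene
    structure on the circle (intergenic spacers, overlaps, strand census,
    start/stop codon classes, origin-of-replication stem-loops), computes
    per-region and per-codon-position base composition with AT- and
    GC-skews, tabulates codon usage and relative synonymous codon usage
    (RSCU), estimates pairwise and gene-wise Ka/Ks by the Nei-Gojobori
    (1986) counting method with Jukes-Cantor correction, and builds
    distance-based (JC + neighbor-joining) trees from concatenated
    protein-coding genes. Includes a synthetic-data generator that
    emulates a 16.6 kb fish mitogenome with the standard 37-gene order
    and codon-model sequence evolution under purifying selection, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
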