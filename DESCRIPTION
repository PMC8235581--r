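Package: genosig
Title: Comparative Genomic Signatures of Closely Related Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end comparative genomics of small sets of closely related
    bacterial genomes: reciprocal-best-hit orthology and core-genome
    accounting, fragment-recruitment average nucleotide identity (ANIb) and
    average amino-acid identity (AAI), single-copy-gene supermatrix phylogeny
    with bootstrap support, multiheme c-type cytochrome profiling by
    heme-binding (CXXCH) motif counting, chemotaxis gene cataloguing with MCP
    heptad-class assignment and operon/cluster typing, insertion-sequence
    transposase census, and Bray-Curtis clustering of the resulting signature
    matrices. Ships a deterministic annotated-genome simulator that plants
    each signature feature with a machine-readable truth table, so the whole
    pipeline is testable without downloading genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    data.table,
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
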