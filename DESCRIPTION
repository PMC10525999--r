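Package: mitopartite
Title: Multipartite Plant Mitogenome Structure, Heteroplasmy and
    Plastid-Insertion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative population analysis of multipartite plant
    mitochondrial genomes. Provides a seeded synthetic-population forge
    (multi-molecule circular/linear genomes with long repeats, a shared
    plastid-derived insertion, differential loci and low-frequency
    heteroplasmy), detection of long exact repeats and enumeration of
    recombination-generated genome conformations with junction support,
    coverage-based copy-number segmentation and linear-end taper detection,
    filtered heteroplasmy and variant calling with germplasm typing and
    population summary tables, quartet-parsimony assignment of the organelle
    lineage in which variants inside a shared chloroplast-derived insertion
    arose, neighbor-joining trees on Jukes-Cantor distances over concatenated
    marker windows, MISA-style microsatellite scanning, and in-silico PCR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
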