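Package: n4core
Title: Core-Genome and Metagenome-Recruitment Analysis of N4-like Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the comparative-genomics workflow
    used to delineate the core genome of the N4-like phage genus and to estimate
    the environmental abundance of N4-like roseophage genes in marine
    metagenomes. Provides gene-prediction amalgamation, all-vs-all protein
    similarity with Karlin-Altschul statistics, bidirectional-best-hit graphs
    with Markov clustering into ortholog families, pan-genome partitioning
    (core, clade-conserved, clade-exclusive, genome-unique gene sets),
    concatenated core-gene neighbor-joining phylogenies with Poisson-corrected
    distances and bootstrap consensus, six-frame translated fragment
    recruitment with a reciprocal top-k viral-panel filter and normalized
    relative abundance, and a synthetic phage-genome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
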