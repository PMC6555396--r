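Package: camphy
Title: Alignment-Free Phylogenetics from Codon Aversion Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers phylogenies without sequence alignment by comparing
    codon aversion motifs, the sets of codons absent from individual coding
    sequences, across all genes of each species. Builds per-species motif
    profiles from CDS FASTA files, computes an overlap-coefficient distance
    between species with a minimum-overlap safeguard for small genomes,
    reconstructs unrooted trees by neighbor-joining, and scores recovered
    trees against references with a bipartition-based edge-similarity
    percentage. Includes motif summary statistics, a seeded simulator that
    evolves codon aversion along a known tree for end-to-end validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
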