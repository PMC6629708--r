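Package: synapodiag
Title: Diagnostic DNA Characters and Clade Support for Molecular Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-based diagnoses of higher taxa from partitioned
    exon alignments. Scans multiple sequence alignments for clade-diagnostic
    nucleotide positions (synapomorphies that are invariant within a focal
    clade and differ from a mostly invariant outgroup state), ranks them by
    missing data and sequencing coverage, and renders them in the compact
    scaffold.gene.exon character notation used in taxonomic diagnoses.
    Includes a sequence simulator that plants known synapomorphies along a
    phylogeny for benchmarking, COI-barcode p-distance computation with
    single-linkage specimen association, neighbor-joining tree estimation
    with column-bootstrap clade support, and the multi-tree support rule
    used to justify subfamily rank.
License: MIT
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
    igraph,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
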