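Package: haplobook
Title: Haplotype-Aware De Novo Assembly of Diploid Genomes from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A divide-and-conquer haplotype-aware assembler for diploid genomes
    sequenced with long reads (PacBio HiFi, PacBio CLR, Oxford Nanopore). Reads
    are grouped into seed-centred clusters, each cluster is assembled into an
    ad hoc reference against which heterozygous SNPs are called, and the
    cluster's reads are partitioned into the two local haplotypes by solving
    the weighted minimum error correction (wMEC) problem exactly by dynamic
    programming. The resulting haplotype-specific super reads are assembled
    into haplotigs through an overlap graph with tip removal, transitive
    reduction and simple-path merging. Includes an internal minimizer-based
    all-vs-all overlapper with PAF import/export, pileup polishing, a synthetic
    diploid genome and long-read simulator with ground-truth haplotype labels,
    and evaluators for haplotype coverage, switch error rate, N50/NG50/NGA50,
    duplication ratio and assembly QV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    igraph,
    ggplot2,
    generics,
    withr,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
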