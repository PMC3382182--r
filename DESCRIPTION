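Package: picometa
Title: Analytics for Flow-Sorted Single-Population Metagenomes
Version: 0.1.0
Authors@R:
    person("picometa", "developers", email = "picometa@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing metagenomes of flow-sorted, whole-genome
    amplified picoeukaryote populations sequenced with long-read
    pyrosequencing chemistry. Provides a ground-truth-tracked synthetic data
    generator (multi-chromosome GC-heterogeneous reference genomes, genotype
    mixtures with rRNA intron polymorphism, contaminants, and MDA-style
    amplification-biased read sets), reference-guided read mapping with
    per-chromosome coverage/identity analytics, ortholog-threshold
    translated-search taxonomic assignment with LCA and leave-one-out
    false-positive validation, filtered variant calling with
    minimum-haplotype decomposition and intron genotyping, and masked
    multi-genome similarity reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
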