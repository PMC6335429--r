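Package: scaffaudit
Title: Coverage, Linkage-Disequilibrium and Synteny Auditing of Genome Assembly Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit chromosome-level genome assemblies: gap and
    un-gapped contig extraction from FASTA with N50 and cross-assembly
    contiguity comparisons, classification of scaffolder-introduced contig
    breaks by long-read depth of coverage, linkage-disequilibrium (LDU) map
    construction over placed SNPs with LD-jump mis-join detection and
    synthetic scaffold join testing, synteny-conservation classification of
    contig joins from filtered flank alignment hits, structural-difference
    overlap between assemblies and haplotigs, and repeat, centromere and
    telomere profiling from RepeatMasker annotations. Includes a seeded
    simulator of diploid genomes, LD-structured populations, coverage tracks
    and defect truth sets so every stage can be exercised end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
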