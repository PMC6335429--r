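# scaffaudit

Audit tools for chromosome-level genome assemblies.

Modern mammalian assemblies are built from long reads (FALCON-Unzip-style
contigs) and scaffolded with proximity-ligation data (Chicago, Hi-C). The
scaffolder both joins and *breaks* contigs, and some of those breaks are
wrong — typically introduced where the contig assembly switches haplotype
phase. Other joins are genuine mis-assemblies that fuse sequence from
different chromosomes. `scaffaudit` implements the computational audit
that separates the two:

- **Coverage audit of breaks.** For every scaffolder break, the median
  long-read depth in a 50 kb window centred on the breakpoint is compared
  with the genome-wide median. A break in a region of *expected* coverage
  is a false break (candidate for rejoining); unusually **high** coverage
  indicates collapsed repeats or segmental duplication, unusually **low**
  coverage a chimeric join. `rejoin_false_breaks()` undoes the false ones.
- **LD-map validation of joins.** From unphased population genotypes
  (0/1/2 SNP matrix with placements) an additive linkage-disequilibrium
  map is built: each inter-SNP interval gets an LDU increment, either from
  a least-squares fit of the Malecot decay
  `rho(d) = (1 - L) * M * exp(-eps * d) + L` over nearby SNP pairs
  (`mode = "malecot"`), or from `-log` of the adjacent-pair |D'|
  (`mode = "r2decay"`). Contiguous sequence accumulates LDU slowly; a
  mis-join shows an *LD jump* — an interval increment above an outlier
  threshold θ (Tukey fence on trusted scaffolds, or the published constant
  0.275). `test_synthetic_joins()` joins two scaffolds in all four
  orientations and asks which, if any, preserves LD across the junction.
- **Synteny validation of joins.** The 3 kb flanks of every gap are
  aligned to related genomes (BLAST outfmt 6 is consumed; hits filtered at
  e-value < 1e-10, identity > 85%, length ≥ 1 kb). A join has conserved
  synteny if both flanks hit the same target chromosome, same strand,
  within 1 Mb. `combine_evidence()` calls a join a mis-assembly candidate
  only when an LD jump *and* interrupted synteny coincide.
- **Contiguity statistics.** Gap calling (maximal N runs, minimum 3 Ns),
  un-gapped contig decomposition, N50, and one-sided Wilcoxon rank-sum
  comparison of contig-length distributions with Bonferroni correction —
  plus the reported-number arithmetic of assembly papers (coverage folds,
  percentages, phred QV error-fold conversions).
- **Structural-difference overlap.** Assemblytics-style call sets are
  matched by 50% reciprocal overlap (insertions by breakpoint distance and
  size ratio) into Venn partitions, per-category base totals and
  size-binned counts.
- **Repeat profiling.** RepeatMasker `.out` parsing, length distributions
  of long (> 2 kb), well-conserved (identity > 60%) repeat families,
  centromeric-satellite span and chromosome-end proximity, and telomere
  motif (`TTAGGG`) searches in 100 kb end windows.
- **A closed-loop simulator.** `sim_config()` / `simulate_genome()` /
  `simulate_population()` / `inject_defects()` generate a seeded toy
  diploid genome with planted satellite/LINE/telomere arrays, a
  rearranged related genome with ideal flank hits, block-wise-LD
  genotypes, coverage tracks, scaffolder breaks and mis-joins — each with
  an exact truth record, so every stage above is testable end to end with
  no downloads.

Everything takes and returns tibbles and composes with the pipe; fitted
objects (`ld_map`, `rank_test`) have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example

Simulate an assembly with injected defects (one cross-chromosome
mis-join, 10 false breaks at flat coverage, 5 true breaks over collapsed
repeats) and audit it:

```r
library(scaffaudit)

cfg <- sim_config(seed = 1)
sim <- simulate_genome(cfg)
pop <- simulate_population(cfg, sim)
def <- inject_defects(cfg, sim, pop)

# 1. classify scaffolder breaks by long-read coverage
calls <- audit_breaks(def$breaks, def$coverage)
summarize_breaks(calls)
#> # A tibble: 2 × 4
#>   source  n_breaks n_false n_supported
#>   <chr>      <int>   <int>       <int>
#> 1 chicago       14       9           5
#> 2 hic            1       1           0

# 2. LD-unit map of the suspect scaffold and its jumps
ldm <- build_ld_map(def$genotypes, "scaffold_mj1", mode = "r2decay")
ldm
#> ld_map of scaffold_mj1 (r2decay): 113 SNPs, map length 3.005 LDU
jumps <- detect_jumps(ldm, theta = 0.275)
jumps[jumps$flagged, c("left_pos", "right_pos", "delta")]
#> # A tibble: 1 × 3
#>   left_pos right_pos delta
#>      <dbl>     <dbl> <dbl>
#> 1   198021    200315  2.49

# 3. synteny verdicts + combined evidence
synteny <- validate_assembly_joins(def$joins, def$hit_tables)$overall
flags <- ld_flags_for_joins(jumps, def$joins)
evidence <- combine_evidence(flags, synteny)
evidence[evidence$class == "candidate", ]
#> # A tibble: 1 × 4
#>   join_id ld_flagged synteny_status class
#> 1 join_01 TRUE       not_conserved  candidate
```

All 10 + 5 injected breaks are classified correctly, the single flagged
LD jump brackets the true junction (planted at position 200,000), and the
one join carrying both lines of evidence is exactly the injected
mis-join (`def$truth$misjoins`). The `plot_break_audit()`,
`autoplot(ldm)`, `plot_gap_counts()` and `plot_sv_bases()` helpers draw
the corresponding figures.

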