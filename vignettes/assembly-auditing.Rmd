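---
title: "Auditing chromosome-level assemblies: coverage, LD maps and synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing chromosome-level assemblies: coverage, LD maps and synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffaudit)
```

## The problem

Long-read contig assemblies of diploid genomes are scaffolded with
proximity-ligation data (Chicago for short range, Hi-C for chromosome
range). The scaffolder's likelihood model both joins contigs and breaks
contigs it believes are chimeric. Two distinct error modes follow:

1. **False breaks.** Where the contig assembly switches haplotype phase,
   proximity reads mapped against a single haplotype look discordant and
   the scaffolder breaks a perfectly good contig. These breaks should be
   rejoined.
2. **Mis-joins.** Conversely, a scaffold may fuse sequence that belongs
   to different chromosomes, or place a contig in the wrong orientation.

Neither error is visible from the assembly alone. `scaffaudit`
implements the three independent evidence streams used to tell them
apart — long-read depth of coverage at breakpoints, population linkage
disequilibrium across joins, and conservation of synteny with related
genomes — together with the contiguity, structural-difference and repeat
statistics used to benchmark the corrected assembly.

## Coverage audit of scaffolder breaks

`audit_breaks()` takes the scaffolder's break report and a long-read
depth track (bedGraph). For each break it computes the **median** depth
in a window of `window_size` bp (default 50 kb) centred on the
breakpoint — the median, not the mean, so isolated spikes do not move
the statistic — and divides by the base-weighted genome median.
Categories follow two configurable ratio thresholds:

| category   | rule                   | default   | interpretation                          |
|------------|------------------------|-----------|-----------------------------------------|
| `expected` | low < ratio < high     | (0.25, 1.75) | false break (phase switch); rejoin    |
| `high`     | ratio ≥ high_threshold | 1.75      | collapsed repeat / segmental duplication |
| `low`      | ratio ≤ low_threshold  | 0.25      | chimeric join                            |

The source study defines the three categories but not numeric bounds, so
the defaults here are the package's own calibration: collapsed haplotypes
or duplications roughly double depth (1.75 leaves headroom for noise),
and chimeric junctions approach zero coverage (0.25 likewise). Both are
arguments of `audit_breaks()`; classification uses only the ratio, so it
is invariant under uniform depth scaling. Windows truncated by a sequence
end are computed on the truncated span and flagged `clipped` rather than
refused, which keeps breaks near scaffold termini auditable.

A read-pair-distance column in the break report, if present, is carried
through to the output untouched: it was inspected alongside coverage in
the original manual curation, but no decision rule for it was ever
stated, so it never influences the verdict here.

`rejoin_false_breaks()` merges the two components abutting each
false-break position, in their original order and orientation, and is by
construction a left inverse of break injection: rejoining all and only
the truth-labelled false breaks of a simulated assembly restores the
pre-break layout exactly (sequence-identical scaffolds, original
component names).

## LD-unit maps and jump detection

With SNP-array genotypes for a few hundred individuals, linkage
disequilibrium decays smoothly along a correctly assembled scaffold and
is absent between chromosomes. `build_ld_map()` turns this into an
additive coordinate: each interval between adjacent mapped SNPs receives
a non-negative LDU increment, and `ldu[i]` is the cumulative sum
(non-decreasing by construction).

Pairwise association is |D'| (or |r|) from EM-estimated two-locus
haplotype frequencies on pairwise-complete unphased genotypes; only the
double heterozygote is phase-ambiguous and its coupling/repulsion split
is re-estimated each EM round. SNPs with minor-allele frequency below
0.05 or more than 20% missingness are dropped first — association
estimates are unstable otherwise; both cutoffs are arguments.

Two increment estimators are provided:

- `mode = "malecot"` (default): for each interval, the exponential decay
  `rho(d) = (1 - L) * M * exp(-eps * d) + L` is least-squares fitted
  (box-constrained: L, M in [0, 1], eps ≥ 0) to the associations of all
  SNP pairs spanning the interval within a `window = 10`-SNP band; the
  increment is `eps_hat * d`. This follows the classical swept-radius
  construction of LDU maps; the windowing and fitting details of the
  original LDMAP program are not published with the study, so these are
  implementation choices calibrated to reproduce the qualitative
  behaviour the audit relies on.
- `mode = "r2decay"`: the increment is `-log(max(assoc_adjacent,
  floor))` from the adjacent pair alone (floor 0.05, so one interval
  contributes at most ~3 LDU). A fast surrogate with the same contrast:
  complete LD gives 0, independence gives the cap. The replicated
  recovery suites use this mode; the Malecot mode is exercised alongside
  it and localizes the same junctions.

An interval whose association is inestimable (monomorphic SNP after
filtering) contributes a zero increment and is flagged `estimable =
FALSE` rather than erroring.

`detect_jumps()` flags intervals whose increment exceeds θ.
`derive_threshold()` offers the Tukey upper fence (Q3 + 1.5 IQR,
requiring ≥ 20 calibration increments from scaffolds believed sound) and
a constant override; 0.275 is the published calibration for the buffalo
90K-chip map and is the default θ wherever one is needed. Flagging is
monotone in θ by construction.

`test_synthetic_joins()` virtually concatenates two scaffolds in all
four orientation configurations (`a+b+`, `a+b-`, `a-b+`, `a-b-`),
mirroring SNP positions for reversed scaffolds, and measures the LDU
increment across the junction from the `k_snps = 10` SNPs nearest each
side. The join is supported when the minimum junction increment falls
below θ; ties break toward the smaller increment, then lexicographic
orientation. Scaffolds carrying fewer than two mapped SNPs are reported
`untestable`, not failed — at array densities only major scaffolds can
be tested.

`combine_evidence()` applies the conjunction rule: a join is a
mis-assembly **candidate** only when it is LD-flagged *and* interrupts
synteny; either signal alone places it on a watch list.

## Synteny classification of joins

`extract_flanks()` takes the `flank = 3000` bp left and right of each
gap (truncated-and-flagged at scaffold ends; all-N flanks are
unalignable). Alignment itself is pluggable — any aligner emitting BLAST
tabular (outfmt 6) works; the simulator emits ideal hit tables so the
test suite needs no aligner binary. `filter_hits()` applies the study's
printed cutoffs with their printed strictness: e-value < 1e-10, identity
> 85%, alignment length ≥ 1 kb. `classify_join()` picks the
best-bitscore hit per flank (ties by e-value, then length) and calls the
join conserved iff both hits share target chromosome and strand and the
distance between their nearest ends (0 when overlapping) is at most
1 Mb. Two refinements are the package's own conservative choices: when a
flank's top two hits land on different chromosomes within 5% bitscore
the flank is ambiguous (repeat-like) and the join is classed
`not_conserved`; and separation is measured end-to-end rather than
midpoint-to-midpoint. The right flank is not reverse-complemented before
searching, so "same strand" is evaluated on raw hit strands.
`validate_assembly_joins()` runs this per related genome and calls a
join synteny-interrupted overall only when *no* target genome conserves
it.

## Contiguity, rank tests and report arithmetic

Gaps are maximal N runs of length ≥ `min_run = 3` — the rule used when
comparing gap counts between assemblies — and un-gapped contigs are their
exact complement (the two partitions always tile each sequence).
Terminal N runs count as gaps by default (`include_terminal = FALSE` to
exclude; published gap counts do not state their convention). Ambiguity
codes other than N are ordinary bases; soft-masking case is not
preserved.

`compare_ungapped_lengths()` is the one-sided Wilcoxon rank-sum test
with continuity correction, computed through `stats::wilcox.test` (the
same environment the original analysis used): W is the first-sample rank
sum minus n1(n1+1)/2, so 0 ≤ W ≤ n1·n2; the exact null distribution is
used for small untied samples and the corrected normal approximation
otherwise; Bonferroni multiplies by the number of comparisons, capped at
1. The remaining helpers are deliberately tiny: `n50()` (always an
element of its input), `coverage_fold()`, `fraction_pct()` (half-up
rounding at the report layer only), `qv_error_fold()`
(`10^(dQV/10)`, multiplicative in QV differences) and
`fold_improvement()`.

## Structural-difference overlap

The study gives no matching rule for "matched with the haplotigs", so
`match_diffs()` uses the community-standard comparison: same category
(configurable) and ≥ 50% reciprocal overlap; insertions, near-zero-width
on the reference, match by breakpoint distance ≤ 100 bp and size ratio
≥ 0.5. Matching is greedy by descending overlap fraction with
deterministic coordinate tie-breaks, each record used at most once, so
partitions conserve counts (`only_a + shared = |A|`) and the shared
count is symmetric. Records outside the 50–10,000 bp analysis window are
parsed and flagged, not silently dropped.

## Repeats, centromeres, telomeres

RepeatMasker `.out` rows become 0-based half-open features with identity
= 100 − divergence; the "> 60% identity" and "> 2 kb" profile filters
are strict inequalities. Centromere calls report both whether any single
`Satellite/centr` feature spans > 5 kb and whether any such feature
intersects the first or last 100 kb of the chromosome (`merged = TRUE`
switches spans to merged arrays — the published "> 5 kb" does not say
which; single-feature is the default). Telomere detection scans both
strands (`TTAGGG` / `CCCTAA`) in the 100 kb end windows and requires a
tandem run of ≥ 10 motif copies — the study gives motif and window but
no copy threshold; scattered single hexamers plainly should not count.
Base-fraction summaries merge overlapping annotations per class before
dividing, so double-annotated bases are counted once.

## The simulator: what it emulates and what it does not

The simulator exists so that every stage has a closed-loop test with an
exact truth record. Defaults are desk scale — three 400 kb chromosomes,
200 individuals, ~120 SNPs per chromosome — chosen so the replicated
suites run in minutes while preserving the structure each method needs:

- **Genome** (`simulate_genome()`): chromosome 1 is sub-metacentric
  (centromeric satellite array at the mid-chromosome fusion junction),
  the rest acrocentric (array within 100 kb of the start); two
  chromosomes carry ~6.6 kb arrays and one a ~3.9 kb array so the
  "> 5 kb" rule has both outcomes. LINE-like elements of varying length
  and divergence include one decayed copy below the 60% identity cutoff
  and one below the 2 kb length cutoff. Telomeric ends are off by
  default, mirroring the empirical finding that none resolved;
  `telomere_copies` plants them for positive controls.
- **Related genome**: the base genome with 5% point divergence and every
  even-numbered chromosome inverted whole. Whole-chromosome flips
  exercise strand handling while guaranteeing no rearrangement breakpoint
  falls near a true join — the regime in which synteny-based mis-join
  detection is expected to have high recall and near-zero false alarms.
  Ideal flank-hit tables are derived from the known segment mapping.
- **Population** (`simulate_population()`): within 50 kb blocks,
  haplotypes descend from two complementary founders (complete LD, |D'|
  = 1, allele frequency 1/2); gametes re-draw their founder at block
  boundaries with probability 0.1 (inter-block |D'| ≈ 0.9, LDU increment
  ≈ 0.1, comfortably under θ = 0.275); chromosomes assort independently
  (junction increments ≈ 2.5–3). 2% missingness.
- **Defects** (`inject_defects()`): one cross-chromosome mis-join (half
  of chr1 fused to half of chr2), the orphaned halves as their own
  scaffolds, and the last chromosome split into two scaffolds — the true
  partners for synthetic-join testing. Ten false breaks at flat-coverage
  sites and five true breaks centred on 40 kb collapsed-repeat regions
  (depth × 2.5; the region must exceed half the 50 kb audit window for
  the median to register). Coverage is Normal(depth, 2) per 500 bp bin.
  Paired SV call sets share a planned 12.5% of set A (jitter ≤ 20 bp),
  with B-only records screened against accidental matches so the planted
  share is recoverable to ± 1 record.

Everything is a deterministic function of the config (one seed,
consecutive sub-seeds per stage), and every emitted defect has exactly
one truth record.

What the simulator does **not** model — and what passing its suites
therefore does not show about real data: read-level error and mapping
bias (coverage is drawn, not aligned), genotyping error and population
structure beyond the founder-block model, gradual LD decay within
blocks, repeat-mediated ambiguous flank alignments (ideal hit tables
have one true hit), gap-length uncertainty, and real SV callers'
breakpoint noise beyond the planted jitter. The replicated recovery
rates (sensitivity ≥ 0.9, false-positive rate ≤ 0.1, localization within
one interval) are artifact acceptance thresholds for this package under
these conditions, not claims about any particular dataset.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; 1-based inclusive only
  at the AGP and BLAST boundaries (minus-strand BLAST hits, encoded as
  start > end, are normalised on read).
- Weighted medians over bedGraph rows are exact (equivalent to expanding
  to per-base depths), with even-count midpoints averaged.
- The Malecot fit starts eps at 0.01 on plateaus (mean association
  > 0.8) and 1 otherwise, bounded in [0, 100] per kb; increments are
  clamped at 0 so LDU coordinates cannot decrease.
- Empty inputs return empty, correctly-typed tibbles (`find_gaps` on
  gap-free input, `audit_breaks` on an empty report, `read_diff_bed` on
  an empty file); undefined quantities (association at a monomorphic
  SNP) are `NA` with a flag, not errors; genuinely contradictory inputs
  (a scaffold joined to itself, inverted thresholds, unknown SV
  categories) are errors.
- `fraction_pct()` rounds half-up, matching how reported percentages are
  printed; all internal values stay unrounded.

## Replicated problem sizes

The acceptance suites run the full pipeline on 30 simulation replicates
at the default desk scale (1.2 Mb genome, 200 individuals, 15 breaks, 1
mis-join, ~360 SNPs), the oracle suites on 1000 random N-injected
strings, 100 random N50 inputs (n ≤ 20) and 30 random rank-sum cases
(n1, n2 ≤ 8). These sizes were chosen as the package's own test budget;
`scripts/acceptance.R` re-runs the same measurements from a single
command-line seed.

## Known limitations

- The LDU estimator is calibrated for contrast (jump vs no jump), not
  for absolute LDU lengths; map lengths are not comparable to
  chip-specific published maps.
- Synthetic-join testing assumes the junction-adjacent SNPs are well
  placed; placement error migrates the signal to neighbouring intervals
  (the localization criterion tolerates ± 1 interval for this reason).
- The toy flank aligner and ideal hit tables sidestep repeat-induced
  multi-mapping; with real BLAST output the 5% bitscore ambiguity rule
  becomes load-bearing and conservative.
- Insertion matching by breakpoint distance does not attempt sequence
  comparison of the inserted allele.
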