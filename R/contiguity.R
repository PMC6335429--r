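#' Assembly N50
#'
#' Smallest length L such that sequences of length >= L sum to at least half
#' the total assembled bases. Always an element of the input.
#'
#' @param lengths Positive integer vector of sequence lengths (bp).
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50: empty length vector")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]])
}

#' Summarize an assembly's contiguity
#'
#' @param assembly Assembly tibble from [read_fasta()].
#' @param min_run Gap-qualifying N-run length.
#' @return One-row tibble: `n_sequences`, `n_gaps`, `N50` (scaffold N50, bp),
#'   `contig_N50` (un-gapped contig N50, bp), `total_length` (bp), and a
#'   list-column `gaps_per_sequence` of per-sequence gap counts.
#' @export
contiguity_summary <- function(assembly, min_run = 3) {
  gaps <- find_gaps(assembly, min_run = min_run)
  ctgs <- split_ungapped(assembly, min_run = min_run)
  per_seq <- dplyr::count(gaps, .data$seq_id, name = "n_gaps")
  per_seq <- dplyr::left_join(tibble::tibble(seq_id = assembly$id), per_seq,
                              by = "seq_id")
  per_seq$n_gaps[is.na(per_seq$n_gaps)] <- 0L
  tibble::tibble(
    n_sequences = nrow(assembly),
    n_gaps = nrow(gaps),
    N50 = n50(assembly$length),
    contig_N50 = n50(ctgs$length),
    total_length = sum(as.numeric(assembly$length)),
    gaps_per_sequence = list(per_seq))
}

#' One-sided rank-sum comparison of un-gapped contig lengths
#'
#' Wilcoxon rank-sum test with continuity correction, one-sided, asking
#' whether sample `a` is stochastically larger (alternative `"greater"`,
#' the contiguity question) with a Bonferroni adjustment for the number of
#' pairwise comparisons run alongside this one. The W statistic follows the
#' first-sample convention (rank sum of `a` minus n1(n1+1)/2), so W ranges
#' over [0, n1*n2].
#'
#' @param lengths_a,lengths_b Numeric vectors of lengths (bp).
#' @param alternative One of `"greater"`, `"less"`, `"two.sided"`.
#' @param n_tests Bonferroni multiplier (number of comparisons).
#' @return A `rank_test` object; see [tidy.rank_test()].
#' @export
compare_ungapped_lengths <- function(lengths_a, lengths_b,
                                     alternative = "greater", n_tests = 1) {
  stopifnot(length(lengths_a) > 0, length(lengths_b) > 0, n_tests >= 1)
  # exact null distribution for small untied samples, continuity-corrected
  # normal approximation otherwise (wilcox.test's own switch at n = 50)
  wt <- suppressWarnings(stats::wilcox.test(
    lengths_a, lengths_b, alternative = alternative, correct = TRUE))
  structure(list(
    W = unname(wt$statistic),
    p_raw = wt$p.value,
    p_adjusted = min(1, wt$p.value * n_tests),
    n1 = length(lengths_a), n2 = length(lengths_b),
    alternative = alternative, n_tests = n_tests),
    class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (continuity-corrected), alternative = %s\n",
    x$alternative))
  cat(sprintf("  n1 = %d, n2 = %d, W = %g\n", x$n1, x$n2, x$W))
  cat(sprintf("  p = %.4g (Bonferroni x%d: %.4g)\n",
              x$p_raw, x$n_tests, x$p_adjusted))
  invisible(x)
}

#' @rdname tidy_scaffaudit
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$W, p.value = x$p_raw,
                 p.adjusted = x$p_adjusted, n1 = x$n1, n2 = x$n2,
                 alternative = x$alternative, method = "wilcoxon rank-sum")
}

#' @rdname tidy_scaffaudit
#' @export
glance.rank_test <- function(x, ...) tidy.rank_test(x)

#' Sequencing coverage fold
#'
#' @param total_bases Total sequenced bases (bp).
#' @param genome_size Assumed genome size (bp).
#' @return `total_bases / genome_size`, unrounded.
#' @export
coverage_fold <- function(total_bases, genome_size) {
  stopifnot(genome_size > 0)
  total_bases / genome_size
}

#' Percentage of a whole, rounded half-up
#'
#' @param part,whole Non-negative numerator and positive denominator.
#' @param ndigits Digits to round to (half-up, report convention).
#' @return `100 * part / whole` rounded half-up to `ndigits`.
#' @export
fraction_pct <- function(part, whole, ndigits = 1) {
  stopifnot(whole > 0, part >= 0)
  round_half_up(100 * part / whole, ndigits)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Fold-change in substitution errors implied by two QVs
#'
#' QV is the phred-scaled probability of an incorrect base substitution,
#' QV = -10 log10(error rate); a difference of dQV corresponds to
#' 10^(dQV/10)-fold fewer errors.
#'
#' @param qv_low,qv_high The two quality values.
#' @return `10^((qv_high - qv_low) / 10)`.
#' @export
qv_error_fold <- function(qv_low, qv_high) {
  stopifnot(is.finite(qv_low), is.finite(qv_high))
  10^((qv_high - qv_low) / 10)
}

#' Fold improvement of a metric over a previous value
#' @param new_value,old_value The two values; `old_value > 0`.
#' @return `new_value / old_value`.
#' @export
fold_improvement <- function(new_value, old_value) {
  stopifnot(old_value > 0)
  new_value / old_value
}
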