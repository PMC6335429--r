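#' Bundle a genotype matrix with SNP placements
#'
#' @param geno Integer matrix, individuals in rows, SNPs in columns; entries
#'   0/1/2 copies of the reference allele, `NA` for missing. Column names,
#'   if present, must match `snps$snp_id`.
#' @param snps Tibble with `snp_id`, `scaffold_id`, `position` (bp); one row
#'   per genotype column, positions strictly increasing within a scaffold.
#' @return A `genotype_set` object.
#' @export
genotype_set <- function(geno, snps) {
  stopifnot(is.matrix(geno), ncol(geno) == nrow(snps))
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotypes must be coded 0/1/2 or NA")
  }
  snps <- tibble::as_tibble(snps)
  ord <- order(snps$scaffold_id, snps$position)
  snps <- snps[ord, ]
  geno <- geno[, ord, drop = FALSE]
  for (sid in unique(snps$scaffold_id)) {
    p <- snps$position[snps$scaffold_id == sid]
    if (any(diff(p) <= 0)) {
      stop("SNP positions not strictly increasing on ", sid)
    }
  }
  colnames(geno) <- snps$snp_id
  structure(list(geno = geno, snps = snps), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d individuals x %d SNPs on %d scaffold(s)\n",
              nrow(x$geno), ncol(x$geno),
              length(unique(x$snps$scaffold_id))))
  invisible(x)
}

# EM estimate of two-locus haplotype frequencies from unphased genotypes.
# Only the double heterozygote is phase-ambiguous; its expected split between
# coupling (AB/ab) and repulsion (Ab/aB) pairs is re-estimated each round.
em_haplotype_freqs <- function(gA, gB, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  n <- length(gA)
  if (n < 2) return(NULL)
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NULL) # monomorphic
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[gA[i] + 1L, gB[i] + 1L] <- cnt[gA[i] + 1L, gB[i] + 1L] + 1
  ndh <- cnt[2, 2]
  # unambiguous haplotype counts
  base_AB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  base_Ab <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  base_aB <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2]
  base_ab <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    w <- if (denom > 0) unname(p["AB"] * p["ab"] / denom) else 0.5
    cAB <- base_AB + w * ndh
    cAb <- base_Ab + (1 - w) * ndh
    caB <- base_aB + (1 - w) * ndh
    cab <- base_ab + w * ndh
    p_new <- c(cAB, cAb, caB, cab) / (2 * n)
    names(p_new) <- names(p)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  list(p = p, pA = pA, pB = pB, n = n)
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Haplotype frequencies are estimated from unphased genotypes by EM
#' (pairwise-complete observations) and summarised as |D'| (default) or |r|.
#'
#' @param genotypes A [genotype_set()].
#' @param i,j SNP indices or `snp_id`s.
#' @param measure `"dprime"` or `"r"`.
#' @return Association in [0, 1], or `NA` if either SNP is monomorphic or
#'   fewer than two pairwise-complete individuals remain.
#' @export
pairwise_association <- function(genotypes, i, j, measure = c("dprime", "r")) {
  measure <- match.arg(measure)
  idx <- function(k) if (is.character(k)) match(k, genotypes$snps$snp_id) else k
  i <- idx(i); j <- idx(j)
  if (i == j) return(1.0)
  fit <- em_haplotype_freqs(genotypes$geno[, i], genotypes$geno[, j])
  if (is.null(fit)) return(NA_real_)
  D <- fit$p["AB"] - fit$pA * fit$pB
  if (measure == "r") {
    denom <- sqrt(fit$pA * (1 - fit$pA) * fit$pB * (1 - fit$pB))
    return(unname(min(1, abs(D) / denom)))
  }
  dmax <- if (D >= 0) {
    min(fit$pA * (1 - fit$pB), (1 - fit$pA) * fit$pB)
  } else {
    min(fit$pA * fit$pB, (1 - fit$pA) * (1 - fit$pB))
  }
  if (dmax <= 0) return(NA_real_)
  unname(min(1, abs(D) / dmax))
}

# Least-squares fit of the Malecot decay rho(d) = (1-L)*M*exp(-eps*d) + L
# over (distance, association) pairs; d in kb, eps in LDU/kb.
fit_malecot <- function(d_kb, assoc) {
  ok <- is.finite(assoc) & is.finite(d_kb)
  d_kb <- d_kb[ok]; assoc <- assoc[ok]
  if (length(assoc) < 3) return(NULL)
  sse <- function(par) {
    pred <- (1 - par[1]) * par[2] * exp(-par[3] * d_kb) + par[1]
    sum((assoc - pred)^2)
  }
  # crude slope-based start for eps keeps the fit off flat plateaus
  eps0 <- if (mean(assoc) > 0.8) 0.01 else 1
  fit <- stats::optim(c(L = 0.05, M = 0.9, eps = eps0), sse,
                      method = "L-BFGS-B",
                      lower = c(0, 0, 0), upper = c(1, 1, 100))
  list(L = fit$par[1], M = fit$par[2], eps = unname(fit$par[3]),
       sse = fit$value)
}

#' Build an LD-unit map along one scaffold
#'
#' Each interval between adjacent mapped SNPs receives a non-negative LDU
#' increment; cumulative LDU coordinates are attached to the SNPs. In
#' `"malecot"` mode the exponential decay model
#' \eqn{\rho(d) = (1-L) M e^{-\epsilon d} + L} is least-squares fitted to
#' the |D'| of all SNP pairs spanning the interval within a `window`-SNP
#' band, and the increment is \eqn{\hat\epsilon \cdot d}. In `"r2decay"`
#' mode the increment is \eqn{-\ln(\max(\rho_{adj}, floor))} from the
#' adjacent-pair association only — a fast surrogate with the same
#' qualitative behaviour (tight LD gives near-zero increments, LD breakdown
#' a large one).
#'
#' @param genotypes A [genotype_set()].
#' @param scaffold Scaffold id to map.
#' @param mode `"malecot"` (default) or `"r2decay"`.
#' @param window SNP-pair band width (pairs at most this many SNPs apart).
#' @param maf_min,max_missing SNP filters applied before mapping.
#' @param floor Association floor for `"r2decay"`.
#' @param measure Association measure passed to [pairwise_association()].
#' @return An `ld_map` object: `scaffold_id`, `mode`, `snps` (tibble
#'   `snp_id`, `position`, `ldu`), `intervals` (tibble `left_snp`,
#'   `right_snp`, `left_pos`, `right_pos`, `d_bp`, `delta`, `estimable`),
#'   `n_dropped`.
#' @export
build_ld_map <- function(genotypes, scaffold, mode = c("malecot", "r2decay"),
                         window = 10, maf_min = 0.05, max_missing = 0.2,
                         floor = 0.05, measure = "dprime") {
  mode <- match.arg(mode)
  sel <- which(genotypes$snps$scaffold_id == scaffold)
  if (length(sel) < 3) stop("need at least 3 SNPs on ", scaffold)
  geno <- genotypes$geno[, sel, drop = FALSE]
  snps <- genotypes$snps[sel, ]
  miss <- colMeans(is.na(geno))
  af <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- miss <= max_missing & maf >= maf_min & !is.na(maf)
  n_dropped <- sum(!keep)
  geno <- geno[, keep, drop = FALSE]
  snps <- snps[keep, ]
  m <- nrow(snps)
  if (m < 3) stop("fewer than 3 SNPs on ", scaffold, " after filtering")
  gs_local <- list(geno = geno, snps = snps)
  class(gs_local) <- "genotype_set"
  # associations for all pairs within the window band
  assoc <- matrix(NA_real_, m, m)
  for (a in seq_len(m - 1)) {
    for (b in seq(a + 1, min(m, a + window))) {
      assoc[a, b] <- pairwise_association(gs_local, a, b, measure = measure)
    }
  }
  pos <- snps$position
  d_bp <- diff(pos)
  deltas <- numeric(m - 1)
  estimable <- rep(TRUE, m - 1)
  if (mode == "r2decay") {
    adj <- assoc[cbind(seq_len(m - 1), seq(2, m))]
    estimable <- is.finite(adj)
    deltas <- ifelse(estimable, -log(pmax(adj, floor)), 0)
  } else {
    for (i in seq_len(m - 1)) {
      a_idx <- seq(max(1, i - window + 1), i)
      b_idx <- seq(i + 1, min(m, i + window))
      pairs <- expand.grid(a = a_idx, b = b_idx)
      pairs <- pairs[pairs$b - pairs$a <= window, ]
      vals <- assoc[cbind(pairs$a, pairs$b)]
      dk <- (pos[pairs$b] - pos[pairs$a]) / 1000
      fit <- fit_malecot(dk, vals)
      if (is.null(fit)) {
        estimable[i] <- FALSE
        deltas[i] <- 0
      } else {
        deltas[i] <- fit$eps * d_bp[i] / 1000
      }
    }
  }
  deltas <- pmax(deltas, 0)
  structure(list(
    scaffold_id = scaffold, mode = mode,
    snps = tibble::tibble(snp_id = snps$snp_id, position = pos,
                          ldu = cumsum(c(0, deltas))),
    intervals = tibble::tibble(
      left_snp = snps$snp_id[-m], right_snp = snps$snp_id[-1],
      left_pos = pos[-m], right_pos = pos[-1],
      d_bp = d_bp, delta = deltas, estimable = estimable),
    n_dropped = n_dropped), class = "ld_map")
}

#' @export
print.ld_map <- function(x, ...) {
  cat(sprintf("ld_map of %s (%s): %d SNPs, map length %.3f LDU\n",
              x$scaffold_id, x$mode, nrow(x$snps), max(x$snps$ldu)))
  invisible(x)
}

#' @rdname tidy_scaffaudit
#' @export
tidy.ld_map <- function(x, ...) {
  dplyr::mutate(x$intervals, scaffold_id = x$scaffold_id, .before = 1)
}

#' @rdname tidy_scaffaudit
#' @export
glance.ld_map <- function(x, ...) {
  tibble::tibble(scaffold_id = x$scaffold_id, mode = x$mode,
                 n_snps = nrow(x$snps), n_intervals = nrow(x$intervals),
                 map_length_ldu = max(x$snps$ldu),
                 max_delta = max(x$intervals$delta),
                 n_dropped_snps = x$n_dropped)
}

#' Derive an LD-jump outlier threshold from calibration intervals
#'
#' Either the Tukey upper fence (Q3 + 1.5 IQR) of LDU increments observed on
#' scaffolds believed sound, or a fixed constant (0.275 is the published
#' calibration for the buffalo 90K-chip map).
#'
#' @param deltas LDU increments from standard (trusted) scaffolds.
#' @param rule `"tukey"` or `"constant"`.
#' @param theta Constant returned when `rule = "constant"`.
#' @return The threshold \eqn{\theta}.
#' @export
derive_threshold <- function(deltas, rule = c("tukey", "constant"),
                             theta = 0.275) {
  rule <- match.arg(rule)
  if (rule == "constant") return(theta)
  deltas <- deltas[is.finite(deltas)]
  if (length(deltas) < 20) {
    stop("need >= 20 calibration deltas for the Tukey rule; ",
         "supply an explicit constant threshold instead")
  }
  q <- stats::quantile(deltas, c(0.25, 0.75), names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Flag LD jumps along an LD map
#'
#' @param ldmap An [build_ld_map()] result.
#' @param theta Outlier threshold (LDU); increments strictly above it are
#'   flagged as potential mis-joins.
#' @return Tibble of intervals with `flagged = delta > theta` and
#'   `scaffold_id`, `theta` columns.
#' @export
detect_jumps <- function(ldmap, theta = 0.275) {
  dplyr::mutate(tidy(ldmap), theta = theta, flagged = .data$delta > theta)
}

orient_snps <- function(snps_tbl, reverse, scaffold_length) {
  if (!reverse) return(snps_tbl)
  out <- snps_tbl[rev(seq_len(nrow(snps_tbl))), ]
  out$position <- scaffold_length - out$position
  out
}

#' Test a synthetic join of two scaffolds in all orientations
#'
#' The two scaffolds are virtually concatenated in each of the four
#' orientation configurations and the LDU increment across the junction is
#' measured from the SNPs nearest the join. A configuration whose junction
#' increment stays below \eqn{\theta} behaves like contiguous sequence and
#' supports joining; independent scaffolds give large increments in every
#' orientation.
#'
#' @param genotypes A [genotype_set()] covering both scaffolds.
#' @param scaffold_a,scaffold_b The two scaffold ids (must differ).
#' @param theta Jump threshold (LDU).
#' @param scaffold_lengths Optional named vector of scaffold lengths (bp);
#'   defaults to last SNP position + 1 kb.
#' @param gap Gap inserted at the junction (bp).
#' @param k_snps SNPs taken from each side of the junction.
#' @param mode,window Passed to [build_ld_map()].
#' @return List with `orientations` (tibble `orientation`, `junction_delta`),
#'   `best_orientation`, `min_delta`, `supported`, `status`
#'   (`"tested"`/`"untestable"`), `theta`.
#' @export
test_synthetic_joins <- function(genotypes, scaffold_a, scaffold_b,
                                 theta = 0.275, scaffold_lengths = NULL,
                                 gap = 1000, k_snps = 10,
                                 mode = "r2decay", window = 10) {
  if (identical(scaffold_a, scaffold_b)) {
    stop("cannot test a scaffold against itself")
  }
  snps <- genotypes$snps
  sa <- snps[snps$scaffold_id == scaffold_a, ]
  sb <- snps[snps$scaffold_id == scaffold_b, ]
  if (nrow(sa) < 2 || nrow(sb) < 2) {
    return(list(orientations = NULL, best_orientation = NA_character_,
                min_delta = NA_real_, supported = NA, status = "untestable",
                theta = theta))
  }
  len <- function(sid, tbl) {
    if (!is.null(scaffold_lengths) && sid %in% names(scaffold_lengths)) {
      scaffold_lengths[[sid]]
    } else {
      max(tbl$position) + 1000
    }
  }
  la <- len(scaffold_a, sa); lb <- len(scaffold_b, sb)
  configs <- tidyr::expand_grid(ori_a = c("+", "-"), ori_b = c("+", "-"))
  res <- purrr::pmap_dfr(configs, function(ori_a, ori_b) {
    a_or <- orient_snps(sa, ori_a == "-", la)
    b_or <- orient_snps(sb, ori_b == "-", lb)
    a_tail <- utils::tail(a_or, k_snps)
    b_head <- utils::head(b_or, k_snps)
    joined <- dplyr::bind_rows(
      dplyr::mutate(a_tail, position = .data$position),
      dplyr::mutate(b_head, position = .data$position + la + gap))
    cols <- match(joined$snp_id, genotypes$snps$snp_id)
    gs_join <- genotype_set(
      genotypes$geno[, cols, drop = FALSE],
      tibble::tibble(snp_id = joined$snp_id, scaffold_id = "synthetic_join",
                     position = joined$position))
    lm <- build_ld_map(gs_join, "synthetic_join", mode = mode, window = window)
    # junction = interval whose left SNP is the last of scaffold_a's tail
    junct <- which(lm$snps$position <= la)
    jd <- lm$intervals$delta[max(junct)]
    tibble::tibble(orientation = paste0("a", ori_a, "b", ori_b),
                   junction_delta = jd)
  })
  res <- dplyr::arrange(res, .data$junction_delta, .data$orientation)
  list(orientations = dplyr::arrange(res, .data$orientation),
       best_orientation = res$orientation[1],
       min_delta = res$junction_delta[1],
       supported = res$junction_delta[1] < theta,
       status = "tested", theta = theta)
}

#' Attach LD-jump flags to contig joins
#'
#' A join (gap) is LD-flagged when any flagged SNP interval spans it; joins
#' on scaffolds without a jump table (too few SNPs) are unflagged.
#'
#' @param jumps Row-bound [detect_jumps()] output (may cover several
#'   scaffolds; needs `scaffold_id`, `left_pos`, `right_pos`, `flagged`).
#' @param joins Tibble with `join_id`, `scaffold_id`, `gap_start`,
#'   `gap_end`.
#' @return Tibble `join_id`, `flagged`.
#' @export
ld_flags_for_joins <- function(jumps, joins) {
  purrr::pmap_dfr(joins[, c("join_id", "scaffold_id", "gap_start",
                            "gap_end")],
                  function(join_id, scaffold_id, gap_start, gap_end) {
    j <- jumps[jumps$scaffold_id == scaffold_id, ]
    hit <- nrow(j) > 0 && any(j$flagged & j$left_pos <= gap_start &
                                j$right_pos >= gap_end)
    tibble::tibble(join_id = join_id, flagged = hit)
  })
}

#' Combine LD-jump and synteny evidence into mis-join candidates
#'
#' A contig join becomes a mis-assembly candidate only when it is both
#' flagged as an LD jump and interrupts conservation of synteny; joins with
#' a single line of evidence are kept on a watch list.
#'
#' @param ld_flags Tibble with `join_id` and logical `flagged`.
#' @param synteny_verdicts Tibble with `join_id` and `status`
#'   (`"conserved"` / `"not_conserved"` / `"unalignable"`).
#' @return Tibble `join_id`, `ld_flagged`, `synteny_status`, `class`
#'   (`"candidate"`, `"watch"`, `"clean"`).
#' @export
combine_evidence <- function(ld_flags, synteny_verdicts) {
  if (!setequal(ld_flags$join_id, synteny_verdicts$join_id)) {
    stop("LD and synteny evidence are keyed by different join ids")
  }
  out <- dplyr::inner_join(
    dplyr::select(ld_flags, "join_id", ld_flagged = "flagged"),
    dplyr::select(synteny_verdicts, "join_id", synteny_status = "status"),
    by = "join_id")
  broken <- out$synteny_status != "conserved"
  dplyr::mutate(out, class = dplyr::case_when(
    ld_flagged & broken ~ "candidate",
    ld_flagged | broken ~ "watch",
    TRUE ~ "clean"))
}
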