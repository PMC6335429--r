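#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12 columns. Target coordinates with start > end encode a minus
#' strand hit; they are normalised to start < end with `strand = "-"`.
#'
#' @param path Path to a tab-separated outfmt-6 file.
#' @return Tibble of hits with `query_id`, `target_chrom`, `pct_identity`,
#'   `align_len`, `mismatch`, `gapopen`, `q_start`, `q_end`, `target_start`,
#'   `target_end`, `strand`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "target_chrom", "pct_identity", "align_len",
            "mismatch", "gapopen", "q_start", "q_end",
            "target_start", "target_end", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols, colClasses = c(
                            "character", "character", rep("numeric", 10)))
  normalize_hits(tibble::as_tibble(df))
}

normalize_hits <- function(hits) {
  minus <- hits$target_start > hits$target_end
  s <- ifelse(minus, hits$target_end, hits$target_start)
  e <- ifelse(minus, hits$target_start, hits$target_end)
  hits$target_start <- s
  hits$target_end <- e
  hits$strand <- ifelse(minus, "-", "+")
  hits
}

#' Extract the flank sequences of a gap
#'
#' The sequences immediately left and right of a gap (default 3 kb each) are
#' what gets aligned to related genomes for the synteny check. Flanks
#' truncated by a scaffold end are flagged; all-N flanks are unalignable.
#'
#' @param record One-row assembly tibble holding the scaffold.
#' @param gap_start,gap_end Gap interval, 0-based half-open.
#' @param flank Flank length (bp).
#' @return Tibble with one row per side: `side`, `start`, `end`, `seq`,
#'   `clipped`, `alignable`.
#' @export
extract_flanks <- function(record, gap_start, gap_end, flank = 3000) {
  stopifnot(nrow(record) == 1L)
  L <- record$length
  if (gap_start < 0 || gap_end > L || gap_end <= gap_start) {
    stop("gap [", gap_start, ",", gap_end, ") outside sequence of length ", L)
  }
  ls <- max(0, gap_start - flank)
  rs <- gap_end
  re <- min(L, gap_end + flank)
  out <- tibble::tibble(
    side = c("left", "right"),
    start = c(ls, rs), end = c(gap_start, re),
    clipped = c(gap_start - flank < 0, gap_end + flank > L))
  out$seq <- substring(record$seq, out$start + 1L, out$end)
  out$alignable <- nchar(out$seq) > 0 & gsub("N", "", out$seq) != ""
  out[, c("side", "start", "end", "seq", "clipped", "alignable")]
}

#' Filter alignment hits by e-value, identity and length
#'
#' Keeps hits with e-value below `max_evalue`, identity above `min_identity`
#' and alignment length of at least `min_len`, ordered by descending
#' bitscore.
#'
#' @param hits Hit tibble from [read_blast_tab()].
#' @param max_evalue,min_identity,min_len The three cutoffs
#'   (defaults 1e-10, 85, 1000).
#' @return Filtered, bitscore-sorted hit tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1e-10, min_identity = 85,
                        min_len = 1000) {
  kept <- hits[hits$evalue < max_evalue & hits$pct_identity > min_identity &
                 hits$align_len >= min_len, , drop = FALSE]
  dplyr::arrange(kept, dplyr::desc(.data$bitscore))
}

best_hit <- function(hits, ambiguity_margin = 0.05) {
  if (!nrow(hits)) return(NULL)
  h <- dplyr::arrange(hits, dplyr::desc(.data$bitscore), .data$evalue,
                      dplyr::desc(.data$align_len))
  if (nrow(h) >= 2 &&
      h$target_chrom[2] != h$target_chrom[1] &&
      h$bitscore[2] >= (1 - ambiguity_margin) * h$bitscore[1]) {
    attr(h, "ambiguous") <- TRUE
  }
  h[1, ]
}

#' Classify one contig join from its flank hits
#'
#' A join has conserved synteny when the best hits of its two flanks land on
#' the same target chromosome, same strand, and within `max_separation`
#' (distance between the nearest hit ends; 0 if they overlap). Flanks whose
#' top two hits are on different chromosomes within 5% bitscore are treated
#' as ambiguous and the join conservatively classed `not_conserved`.
#'
#' @param left_hits,right_hits Already-filtered hit tibbles for the flanks.
#' @param max_separation Maximum target distance (bp), default 1 Mb.
#' @return One-row tibble: `status` (`conserved` / `not_conserved` /
#'   `unalignable`), `target_chrom_left`, `target_chrom_right`,
#'   `strand_left`, `strand_right`, `separation`.
#' @export
classify_join <- function(left_hits, right_hits, max_separation = 1e6) {
  lh <- best_hit(left_hits)
  rh <- best_hit(right_hits)
  empty <- tibble::tibble(status = "unalignable",
                          target_chrom_left = NA_character_,
                          target_chrom_right = NA_character_,
                          strand_left = NA_character_,
                          strand_right = NA_character_,
                          separation = NA_real_)
  if (is.null(lh) || is.null(rh)) return(empty)
  sep <- max(0, max(lh$target_start, rh$target_start) -
               min(lh$target_end, rh$target_end))
  ambiguous <- isTRUE(attr(lh, "ambiguous")) || isTRUE(attr(rh, "ambiguous"))
  conserved <- !ambiguous &&
    lh$target_chrom == rh$target_chrom &&
    lh$strand == rh$strand &&
    sep <= max_separation
  tibble::tibble(status = if (conserved) "conserved" else "not_conserved",
                 target_chrom_left = lh$target_chrom,
                 target_chrom_right = rh$target_chrom,
                 strand_left = lh$strand, strand_right = rh$strand,
                 separation = sep)
}

#' Synteny verdicts for every join of an assembly
#'
#' Runs [classify_join()] for each gap against each related-genome hit
#' table. A join is synteny-interrupted overall only when it is conserved
#' against none of the targets (any one supporting genome suffices).
#'
#' @param gaps Tibble of joins with `join_id` and per-flank query ids
#'   `left_query`, `right_query` matching `query_id` in the hit tables.
#' @param hit_tables Named list of hit tibbles, one per related genome
#'   (already in outfmt-6 form; filtering applied here).
#' @param max_evalue,min_identity,min_len,max_separation Criteria as in
#'   [filter_hits()] and [classify_join()].
#' @return List with `verdicts` (one row per join x target) and `overall`
#'   (`join_id`, `status`: conserved if any target conserves it,
#'   unalignable if unalignable on every target, else not_conserved).
#' @export
validate_assembly_joins <- function(gaps, hit_tables, max_evalue = 1e-10,
                                    min_identity = 85, min_len = 1000,
                                    max_separation = 1e6) {
  stopifnot(length(hit_tables) >= 1, !is.null(names(hit_tables)))
  verdicts <- purrr::imap_dfr(hit_tables, function(hits, genome) {
    hits <- filter_hits(hits, max_evalue, min_identity, min_len)
    purrr::pmap_dfr(gaps[, c("join_id", "left_query", "right_query")],
                    function(join_id, left_query, right_query) {
      v <- classify_join(hits[hits$query_id == left_query, ],
                         hits[hits$query_id == right_query, ],
                         max_separation = max_separation)
      dplyr::mutate(v, join_id = join_id, target_genome = genome, .before = 1)
    })
  })
  overall <- dplyr::summarise(
    dplyr::group_by(verdicts, .data$join_id),
    status = dplyr::case_when(
      any(.data$status == "conserved") ~ "conserved",
      all(.data$status == "unalignable") ~ "unalignable",
      TRUE ~ "not_conserved"),
    .groups = "drop")
  list(verdicts = verdicts, overall = overall)
}
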