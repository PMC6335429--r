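#' Read an Assemblytics-style structural-difference BED
#'
#' Expects at least chrom, start, end plus size and type columns (given by
#' `size_col`/`type_col` indices, defaulting to the Assemblytics layout:
#' column 5 = size, column 7 = type). Category labels are normalised to the
#' six canonical classes. Records outside the 50-10,000 bp analysis window
#' are kept but flagged `out_of_window`.
#'
#' @param path BED-like file path (tab-separated, no header; lines starting
#'   `#` ignored).
#' @param size_col,type_col 1-based column indices of size and type.
#' @param size_window Analysis size window (bp).
#' @return Tibble `ref_seq_id`, `start`, `end`, `size`, `category`,
#'   `out_of_window`.
#' @export
read_diff_bed <- function(path, size_col = 5, type_col = 7,
                          size_window = c(50, 10000)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble::tibble(ref_seq_id = character(), start = integer(),
                          end = integer(), size = integer(),
                          category = character(), out_of_window = logical()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  out <- purrr::map_dfr(f, function(x) {
    tibble::tibble(ref_seq_id = x[1], start = as.integer(x[2]),
                   end = as.integer(x[3]), size = as.integer(x[size_col]),
                   category = x[type_col])
  })
  out$category <- normalize_sv_category(out$category)
  out$out_of_window <- out$size < size_window[1] | out$size > size_window[2]
  out
}

sv_categories <- c("deletion", "insertion", "repeat_contraction",
                   "repeat_expansion", "tandem_contraction",
                   "tandem_expansion")

normalize_sv_category <- function(x) {
  key <- gsub("[ /]+", "_", tolower(trimws(x)))
  if (!all(key %in% sv_categories)) {
    bad <- unique(x[!key %in% sv_categories])
    stop("unknown structural-difference category: ",
         paste(bad, collapse = ", "))
  }
  key
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

#' Match two structural-difference call sets
#'
#' Interval records match when they reciprocally overlap by at least
#' `min_reciprocal_overlap` (and share a category if `same_category`).
#' Insertions, which are near-zero-width on the reference, instead match by
#' breakpoint distance (`<= ins_breakpoint`) and size ratio
#' (`>= ins_size_ratio`). Matching is greedy by descending overlap fraction
#' (ties by coordinate), each record used at most once.
#'
#' @param set_a,set_b Diff tibbles as from [read_diff_bed()].
#' @param min_reciprocal_overlap Reciprocal-overlap fraction for
#'   interval-type records.
#' @param same_category Require identical categories to match?
#' @param ins_breakpoint,ins_size_ratio Insertion matching parameters.
#' @return List with `partition` (one-row tibble `only_a`, `only_b`,
#'   `shared`, `shared_pct_of_a`) and `links` (tibble of matched index
#'   pairs with their overlap fraction).
#' @export
match_diffs <- function(set_a, set_b, min_reciprocal_overlap = 0.5,
                        same_category = TRUE, ins_breakpoint = 100,
                        ins_size_ratio = 0.5) {
  a <- dplyr::mutate(set_a, .idx = dplyr::row_number())
  b <- dplyr::mutate(set_b, .idx = dplyr::row_number())
  cand <- dplyr::inner_join(
    dplyr::select(a, a_idx = ".idx", ref_seq_id = "ref_seq_id",
                  a_start = "start", a_end = "end", a_size = "size",
                  a_cat = "category"),
    dplyr::select(b, b_idx = ".idx", ref_seq_id = "ref_seq_id",
                  b_start = "start", b_end = "end", b_size = "size",
                  b_cat = "category"),
    by = "ref_seq_id", relationship = "many-to-many")
  if (same_category && nrow(cand)) cand <- cand[cand$a_cat == cand$b_cat, ]
  if (nrow(cand)) {
    ins <- cand$a_cat == "insertion" & cand$b_cat == "insertion"
    frac <- reciprocal_overlap(cand$a_start, cand$a_end,
                               cand$b_start, cand$b_end)
    bp_dist <- abs(cand$a_start - cand$b_start)
    size_ratio <- pmin(cand$a_size, cand$b_size) /
      pmax(cand$a_size, cand$b_size)
    ok <- ifelse(ins,
                 bp_dist <= ins_breakpoint & size_ratio >= ins_size_ratio,
                 frac >= min_reciprocal_overlap)
    score <- ifelse(ins, size_ratio, frac)
    cand <- cand[ok, ]
    score <- score[ok]
    o <- order(-score, cand$ref_seq_id, cand$a_start, cand$b_start)
    cand <- cand[o, ]; score <- score[o]
  } else {
    score <- numeric()
  }
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  links <- list()
  for (k in seq_len(nrow(cand))) {
    ia <- cand$a_idx[k]; ib <- cand$b_idx[k]
    if (used_a[ia] || used_b[ib]) next
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    links[[length(links) + 1]] <- tibble::tibble(
      a_idx = ia, b_idx = ib, overlap = score[k])
  }
  links <- if (length(links)) dplyr::bind_rows(links) else
    tibble::tibble(a_idx = integer(), b_idx = integer(), overlap = numeric())
  shared <- nrow(links)
  partition <- tibble::tibble(
    only_a = nrow(a) - shared, only_b = nrow(b) - shared, shared = shared,
    shared_pct_of_a = if (nrow(a)) 100 * shared / nrow(a) else NA_real_)
  list(partition = partition, links = links)
}

#' Total bases of structural differences per category
#'
#' @param diffs Diff tibble.
#' @return Tibble `category`, `total_bp` covering all six categories
#'   (zero-filled).
#' @export
summarize_bases <- function(diffs) {
  base <- tibble::tibble(category = sv_categories, total_bp = 0)
  if (nrow(diffs)) {
    got <- dplyr::summarise(dplyr::group_by(diffs, .data$category),
                            total_bp = sum(as.numeric(.data$size)),
                            .groups = "drop")
    base$total_bp <- got$total_bp[match(base$category, got$category)]
    base$total_bp[is.na(base$total_bp)] <- 0
  }
  base
}

#' Count structural differences per category and size bin
#'
#' @param diffs Diff tibble.
#' @param bin_edges Strictly increasing edge vector; bins are
#'   half-open `[e_i, e_{i+1})` with records beyond the last edge collected
#'   in an `overflow` bin (and below the first edge in `underflow`).
#' @return Tibble `category` x `bin` counts (wide, one column per bin).
#' @export
size_partition <- function(diffs, bin_edges = c(50, 100, 1000, 10000)) {
  stopifnot(all(diff(bin_edges) > 0))
  labs <- c("underflow",
            paste0("[", utils::head(bin_edges, -1), ",",
                   utils::tail(bin_edges, -1), ")"),
            "overflow")
  bin <- labs[findInterval(diffs$size, bin_edges) + 1L]
  counts <- table(factor(diffs$category, levels = sv_categories),
                  factor(bin, levels = labs))
  out <- tibble::as_tibble(as.data.frame.matrix(counts), rownames = "category")
  drop <- vapply(out[-1], function(x) all(x == 0), logical(1))
  keep_cols <- c(TRUE, !drop | colnames(out)[-1] %in% labs[-c(1, length(labs))])
  out[, keep_cols, drop = FALSE]
}
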