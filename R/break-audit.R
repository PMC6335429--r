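#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (seq, start, end, depth; 0-based half-open).
#' @return Coverage tibble `seq_id`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seq_id", "start", "end", "depth"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  tibble::as_tibble(df)
}

# depth-weighted median over bedGraph rows (each row counts end-start bases);
# equivalent to median(rep(depth, weight)) without expansion
weighted_depth_median <- function(depth, weight) {
  o <- order(depth)
  depth <- depth[o]; weight <- as.numeric(weight[o])
  cw <- cumsum(weight)
  half <- sum(weight) / 2
  i <- which(cw >= half)[1]
  if (abs(cw[i] - half) < .Machine$double.eps^0.5 && i < length(depth)) {
    (depth[i] + depth[i + 1]) / 2
  } else {
    depth[i]
  }
}

#' Genome-wide median depth of a coverage track set
#' @param coverage Coverage tibble (`seq_id`, `start`, `end`, `depth`).
#' @return Base-weighted median depth over all sequences.
#' @export
genome_median_depth <- function(coverage) {
  weighted_depth_median(coverage$depth, coverage$end - coverage$start)
}

#' Median depth in a window centred on a position
#'
#' A window of `window_size` bp centred on `position` is intersected with the
#' coverage rows of one sequence; windows running off either sequence end are
#' truncated and flagged.
#'
#' @param coverage Coverage tibble.
#' @param seq_id Sequence to interrogate.
#' @param position Breakpoint position (bp, 0-based).
#' @param window_size Window width (bp); default 50 kb, breakpoint centred.
#' @param genome_median Optional precomputed genome median depth.
#' @return One-row tibble: `window_start`, `window_end`, `window_median`,
#'   `ratio` (window median / genome median), `clipped`.
#' @export
window_stats <- function(coverage, seq_id, position, window_size = 50000,
                         genome_median = NULL) {
  cov <- coverage[coverage$seq_id == seq_id, ]
  if (!nrow(cov)) stop("no coverage for sequence ", seq_id)
  seq_len_bp <- max(cov$end)
  if (position < 0 || position > seq_len_bp) {
    stop("position ", position, " outside [0, ", seq_len_bp, "] on ", seq_id)
  }
  if (is.null(genome_median)) genome_median <- genome_median_depth(coverage)
  if (genome_median <= 0) stop("genome median depth is zero")
  half <- window_size / 2
  ws <- max(0, floor(position - half))
  we <- min(seq_len_bp, ceiling(position + half))
  clipped <- (position - half < 0) || (position + half > seq_len_bp)
  sel <- cov[cov$end > ws & cov$start < we, ]
  if (!nrow(sel)) stop("empty coverage window at ", seq_id, ":", position)
  w <- pmin(sel$end, we) - pmax(sel$start, ws)
  med <- weighted_depth_median(sel$depth, w)
  tibble::tibble(window_start = ws, window_end = we, window_median = med,
                 ratio = med / genome_median, clipped = clipped)
}

#' Classify a break by its coverage ratio
#'
#' Breaks in regions of expected long-read coverage are the hallmark of
#' scaffolder false breaks (typically haplotype phase switches); unusually
#' high coverage indicates collapsed repeats or segmental duplication, and
#' unusually low coverage a chimeric join.
#'
#' @param ratio Window median depth / genome median depth.
#' @param high_threshold Ratio at or above which coverage is "high".
#' @param low_threshold Ratio at or below which coverage is "low".
#' @return `"expected"`, `"high"` or `"low"`.
#' @export
classify_break <- function(ratio, high_threshold = 1.75, low_threshold = 0.25) {
  stopifnot(low_threshold > 0, low_threshold < 1, high_threshold > 1)
  dplyr::case_when(
    ratio >= high_threshold ~ "high",
    ratio <= low_threshold ~ "low",
    TRUE ~ "expected")
}

#' Audit scaffolder breaks against long-read coverage
#'
#' For every reported break a window (default 50 kb) centred on the
#' breakpoint is assessed for depth of coverage. A break in a region of
#' expected coverage is a false break to be rejoined; high- or low-coverage
#' breaks are retained as supported.
#'
#' @param breaks Tibble `scaffold_id`, `position` (bp), `source`
#'   (e.g. `"chicago"`, `"hic"`). Extra columns (such as a read-pair distance
#'   annotation) are carried through untouched.
#' @param coverage Coverage tibble over the pre-break sequences.
#' @param window_size Audit window (bp).
#' @param high_threshold,low_threshold Coverage-ratio category bounds.
#' @return `breaks` with `window_start`, `window_end`, `window_median_ratio`,
#'   `clipped`, `category` and `verdict` (`"false_break"` iff category
#'   `"expected"`, else `"supported"`) appended.
#' @export
audit_breaks <- function(breaks, coverage, window_size = 50000,
                         high_threshold = 1.75, low_threshold = 0.25) {
  if (!nrow(breaks)) {
    return(dplyr::mutate(breaks, window_start = integer(), window_end = integer(),
                         window_median_ratio = numeric(), clipped = logical(),
                         category = character(), verdict = character()))
  }
  gm <- genome_median_depth(coverage)
  stats <- purrr::map2_dfr(breaks$scaffold_id, breaks$position, function(sid, pos) {
    window_stats(coverage, sid, pos, window_size = window_size,
                 genome_median = gm)
  })
  out <- dplyr::bind_cols(breaks, stats[c("window_start", "window_end", "clipped")])
  out$window_median_ratio <- stats$ratio
  out$category <- classify_break(stats$ratio, high_threshold, low_threshold)
  out$verdict <- ifelse(out$category == "expected", "false_break", "supported")
  out
}

#' Summary counts of break verdicts by source
#' @param break_calls Output of [audit_breaks()].
#' @return Tibble `source`, `n_breaks`, `n_false`, `n_supported`.
#' @export
summarize_breaks <- function(break_calls) {
  dplyr::summarise(dplyr::group_by(break_calls, .data$source),
                   n_breaks = dplyr::n(),
                   n_false = sum(.data$verdict == "false_break"),
                   n_supported = sum(.data$verdict == "supported"),
                   .groups = "drop")
}

merged_part_name <- function(source_id, source_start, source_end, source_len) {
  if (!is.na(source_len) && source_start == 0 && source_end == source_len) {
    source_id
  } else {
    sprintf("%s:%d-%d", source_id, source_start, source_end)
  }
}

#' Rejoin false breaks in a post-break layout
#'
#' Breaks judged false are undone: the two components meeting at the break
#' position are re-merged, in their original order and orientation, into a
#' single component. Supported breaks are retained as-is. Layout rows may
#' carry provenance columns (`source_id`, `source_start`, `source_len`, the
#' span each row occupies within its pre-break parent); when present they
#' are used to name merged components so that rejoining every false break of
#' an unbroken parent restores the parent's original id exactly.
#'
#' @param layout_after Layout tibble after scaffolder breaking; each audited
#'   break corresponds to two `W` rows abutting at its position.
#' @param break_calls Tibble with `scaffold_id`, `position` and `verdict`
#'   (from [audit_breaks()], or a truth table).
#' @param components Assembly tibble with the post-break component
#'   sequences (stored in their `+` sense).
#' @return List `layout` (corrected layout tibble) and `components`
#'   (updated component table).
#' @export
rejoin_false_breaks <- function(layout_after, break_calls, components) {
  layout <- layout_after
  has_src <- all(c("source_id", "source_start", "source_len") %in%
                   names(layout))
  comp <- components
  todo <- break_calls[break_calls$verdict == "false_break", , drop = FALSE]
  todo <- dplyr::arrange(todo, .data$scaffold_id, .data$position)
  for (i in seq_len(nrow(todo))) {
    v <- todo[i, ]
    li <- which(layout$scaffold_id == v$scaffold_id &
                  layout$part_type == "W" & layout$end == v$position)
    ri <- which(layout$scaffold_id == v$scaffold_id &
                  layout$part_type == "W" & layout$start == v$position)
    if (length(li) != 1L || length(ri) != 1L) {
      stop("no component pair abutting at ", v$scaffold_id, ":", v$position)
    }
    ori <- layout$orientation[li]
    if (ori != layout$orientation[ri]) {
      stop("inconsistent orientations across break at ", v$scaffold_id, ":",
           v$position)
    }
    id_l <- layout$component_id[li]
    id_r <- layout$component_id[ri]
    seq_l <- comp$seq[comp$id == id_l]
    seq_r <- comp$seq[comp$id == id_r]
    # components are stored in their + sense; a parent placed with "-" shows
    # revcomp(B)+revcomp(A) on the scaffold, so its + sense is right+left
    merged_plus <- if (ori == "-") paste0(seq_r, seq_l) else
      paste0(seq_l, seq_r)
    merged_id <- if (has_src && layout$source_id[li] == layout$source_id[ri]) {
      ss <- min(layout$source_start[li], layout$source_start[ri])
      se <- max(layout$source_start[li] + (layout$end[li] - layout$start[li]),
                layout$source_start[ri] + (layout$end[ri] - layout$start[ri]))
      merged_part_name(layout$source_id[li], ss, se, layout$source_len[li])
    } else {
      paste0(id_l, "+", id_r)
    }
    comp <- dplyr::bind_rows(
      comp[!(comp$id %in% c(id_l, id_r)), ],
      tibble::tibble(id = merged_id, seq = merged_plus,
                     length = nchar(merged_plus)))
    layout$component_id[li] <- merged_id
    layout$end[li] <- layout$end[ri]
    if (has_src) {
      layout$source_start[li] <- min(layout$source_start[li],
                                     layout$source_start[ri])
    }
    layout <- layout[-ri, ]
  }
  list(layout = layout, components = comp)
}
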