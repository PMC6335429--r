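#' Plot per-chromosome gap counts
#'
#' Barplot of gap counts by sequence, optionally faceted by assembly when
#' `gaps` carries an `assembly` column.
#'
#' @param gaps Output of [find_gaps()] (optionally with an `assembly`
#'   column for multi-assembly comparison).
#' @return A ggplot object.
#' @export
plot_gap_counts <- function(gaps) {
  grp <- if ("assembly" %in% names(gaps)) c("assembly", "seq_id") else "seq_id"
  counts <- dplyr::count(gaps, dplyr::across(dplyr::all_of(grp)), name = "n_gaps")
  p <- ggplot2::ggplot(counts,
                       ggplot2::aes(x = .data$seq_id, y = .data$n_gaps)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "gaps") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("assembly" %in% names(gaps)) {
    p <- p + ggplot2::facet_wrap(~assembly, scales = "free_x")
  }
  p
}

#' Plot un-gapped contig length distributions across assemblies
#'
#' @param length_tbl Tibble with `assembly` and `length` (bp) columns.
#' @return A ggplot object (violin + box, log10 length scale).
#' @export
plot_contig_lengths <- function(length_tbl) {
  ggplot2::ggplot(length_tbl,
                  ggplot2::aes(x = .data$assembly, y = .data$length)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "un-gapped contig length (bp)") +
    ggplot2::theme_minimal()
}

#' Plot an LD-unit map
#'
#' Cumulative LDU coordinate against physical position; flagged jump
#' intervals (if `theta` is given) are highlighted.
#'
#' @param object An `ld_map` from [build_ld_map()].
#' @param theta Optional jump threshold to highlight (LDU).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_map <- function(object, theta = NULL, ...) {
  p <- ggplot2::ggplot(object$snps,
                       ggplot2::aes(x = .data$position / 1000, y = .data$ldu)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "position (kb)", y = "cumulative LDU",
                  title = object$scaffold_id) +
    ggplot2::theme_minimal()
  if (!is.null(theta)) {
    fl <- object$intervals[object$intervals$delta > theta, ]
    if (nrow(fl)) {
      p <- p + ggplot2::annotate(
        "rect", xmin = fl$left_pos / 1000, xmax = fl$right_pos / 1000,
        ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red")
    }
  }
  p
}

#' Plot break-audit coverage ratios
#'
#' Coverage ratio of each audited break against the category thresholds.
#'
#' @param break_calls Output of [audit_breaks()].
#' @param high_threshold,low_threshold Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_break_audit <- function(break_calls, high_threshold = 1.75,
                             low_threshold = 0.25) {
  ggplot2::ggplot(break_calls,
                  ggplot2::aes(x = .data$position / 1e6,
                               y = .data$window_median_ratio,
                               colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(low_threshold, 1, high_threshold),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey50") +
    ggplot2::facet_wrap(~scaffold_id, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "window median / genome median") +
    ggplot2::theme_minimal()
}

#' Plot structural-difference totals by category
#'
#' @param diffs Diff tibble (e.g. from [read_diff_bed()]).
#' @return A ggplot object of total bases per category.
#' @export
plot_sv_bases <- function(diffs) {
  tot <- summarize_bases(diffs)
  ggplot2::ggplot(tot, ggplot2::aes(x = .data$category, y = .data$total_bp)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "total bases (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
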