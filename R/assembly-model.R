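#' Read an assembly FASTA into a tibble
#'
#' One row per sequence, residues uppercased. All downstream gap, contiguity
#' and flank operations consume this table.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `seq` (uppercase residues) and `length` (bp).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA at ", path, " contains an empty or missing header")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- unname(toupper(as.character(ss)))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id ", ids[which(nchar(seqs) == 0L)[1]])
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs), length = nchar(seqs))
}

#' Write an assembly tibble to FASTA
#'
#' @param assembly Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path) {
  ss <- Biostrings::BStringSet(rlang::set_names(assembly$seq, assembly$id))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Logical N-mask runs via rle on raw bytes; deliberately not regex-based so
# the regex scan in the test-suite is an independent oracle.
n_runs <- function(seq) {
  isN <- charToRaw(seq) == as.raw(78L) # 'N'
  r <- rle(as.vector(isN))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Locate assembly gaps (N runs)
#'
#' A gap is a maximal run of `N` of length at least `min_run` (default 3,
#' the convention used when comparing gap counts between assemblies).
#' Ambiguity codes other than `N` count as ordinary bases. Terminal N runs
#' count as gaps unless `include_terminal = FALSE`.
#'
#' @param assembly Tibble from [read_fasta()], or any tibble with `id`,`seq`.
#' @param min_run Minimum N-run length to call a gap (bp).
#' @param include_terminal Keep gaps touching either sequence end?
#' @return Tibble `seq_id`, `start`, `end` (0-based half-open), `length`.
#' @export
find_gaps <- function(assembly, min_run = 3, include_terminal = TRUE) {
  stopifnot(min_run >= 1)
  res <- purrr::map2_dfr(assembly$id, assembly$seq, function(id, s) {
    g <- n_runs(s)
    g <- g[g$end - g$start >= min_run, , drop = FALSE]
    if (!include_terminal && nrow(g)) {
      g <- g[g$start != 0L & g$end != nchar(s), , drop = FALSE]
    }
    if (!nrow(g)) return(NULL)
    tibble::tibble(seq_id = id, start = g$start, end = g$end)
  })
  if (!nrow(res)) {
    res <- tibble::tibble(seq_id = character(), start = integer(), end = integer())
  }
  dplyr::mutate(res, length = .data$end - .data$start)
}

#' Decompose sequences into un-gapped contigs
#'
#' The complement of [find_gaps()]: intervals between gap-qualifying N runs.
#' Contig and gap lengths always partition each sequence exactly.
#'
#' @inheritParams find_gaps
#' @return Tibble `seq_id`, `start`, `end` (0-based half-open), `length`.
#' @export
split_ungapped <- function(assembly, min_run = 3) {
  gaps <- find_gaps(assembly, min_run = min_run)
  res <- purrr::map2_dfr(assembly$id, nchar(assembly$seq), function(id, L) {
    g <- gaps[gaps$seq_id == id, ]
    bounds <- c(0L, rbind(g$start, g$end), L)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (!any(keep)) return(NULL)
    tibble::tibble(seq_id = id, start = as.integer(starts[keep]),
                   end = as.integer(ends[keep]))
  })
  if (!nrow(res)) {
    res <- tibble::tibble(seq_id = character(), start = integer(), end = integer())
  }
  dplyr::mutate(res, length = .data$end - .data$start)
}

#' Keep only chromosome-scale sequences
#'
#' Mirrors the pre-filter applied before gap statistics: unplaced,
#' unlocalised, mitochondrial and Y sequences are dropped, autosomes and X
#' retained. Either give an explicit `keep` vector of ids or rely on the
#' naming convention `chr?<number>` / `chr?X` (case-insensitive).
#'
#' @param assembly Assembly tibble (or any tibble with an `id` column).
#' @param keep Optional character vector of ids to retain verbatim.
#' @return The filtered tibble, original order preserved. Warns if empty.
#' @export
filter_chromosomes <- function(assembly, keep = NULL) {
  if (is.null(keep)) {
    sel <- grepl("^(chr)?([0-9]+|X)$", assembly$id, ignore.case = TRUE)
  } else {
    sel <- assembly$id %in% keep
  }
  out <- assembly[sel, , drop = FALSE]
  if (!nrow(out)) warning("filter_chromosomes: no sequences retained")
  out
}

#' Reverse-complement a DNA string
#' @param seq Character scalar of IUPAC DNA.
#' @return Reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

validate_layout <- function(layout) {
  needed <- c("scaffold_id", "part_type", "component_id", "orientation",
              "start", "end")
  stopifnot(all(needed %in% names(layout)))
  for (sid in unique(layout$scaffold_id)) {
    l <- dplyr::arrange(layout[layout$scaffold_id == sid, ], .data$start)
    if (any(l$end <= l$start)) stop("empty or inverted layout row in ", sid)
    if (any(l$start[-1] != l$end[-nrow(l)])) {
      stop("layout of ", sid, " has overlaps or holes")
    }
    if (l$start[1] != 0) stop("layout of ", sid, " does not start at 0")
    if (!all(l$orientation[l$part_type == "W"] %in% c("+", "-"))) {
      stop("orientation must be + or - in ", sid)
    }
  }
  invisible(layout)
}

#' Reconstruct scaffold sequences from a layout
#'
#' A layout is an AGP-like tibble tiling each scaffold with component (`W`)
#' and gap (`N`) rows in 0-based half-open scaffold coordinates. Components
#' with `-` orientation are reverse-complemented. Decomposing the result
#' with [decompose_scaffold()] round-trips the layout.
#'
#' @param layout Tibble with `scaffold_id`, `part_type` (`"W"` or `"N"`),
#'   `component_id`, `orientation`, `start`, `end`.
#' @param components Assembly tibble holding every referenced component.
#' @param gap_char Fill character for gap rows.
#' @return Assembly tibble, one row per scaffold.
#' @export
apply_layout <- function(layout, components, gap_char = "N") {
  validate_layout(layout)
  comp_seq <- rlang::set_names(components$seq, components$id)
  purrr::map_dfr(unique(layout$scaffold_id), function(sid) {
    l <- dplyr::arrange(layout[layout$scaffold_id == sid, ], .data$start)
    pieces <- purrr::pmap_chr(l, function(part_type, component_id, orientation,
                                          start, end, ...) {
      if (part_type == "N") return(strrep(gap_char, end - start))
      if (!component_id %in% names(comp_seq)) {
        stop("component ", component_id, " missing from component table")
      }
      s <- comp_seq[[component_id]]
      if (nchar(s) != end - start) {
        stop("component ", component_id, " length ", nchar(s),
             " != layout span ", end - start)
      }
      if (orientation == "-") revcomp(s) else s
    })
    s <- paste(pieces, collapse = "")
    tibble::tibble(id = sid, seq = s, length = nchar(s))
  })
}

#' Derive the layout of a scaffold from its sequence
#'
#' Components are the un-gapped contigs (named `<scaffold>_ctg<k>`), gaps the
#' qualifying N runs; together they tile the scaffold.
#'
#' @param record One-row assembly tibble (or a row of one).
#' @param min_run Gap-qualifying N-run length.
#' @return List with `layout` (tibble as for [apply_layout()]) and
#'   `components` (assembly tibble of contig sequences, orientation `+`).
#' @export
decompose_scaffold <- function(record, min_run = 3) {
  stopifnot(nrow(record) == 1L)
  ctg <- split_ungapped(record, min_run = min_run)
  gap <- find_gaps(record, min_run = min_run)
  comp_ids <- sprintf("%s_ctg%d", record$id, seq_len(nrow(ctg)))
  rows <- dplyr::bind_rows(
    tibble::tibble(part_type = "W", component_id = comp_ids,
                   orientation = "+", start = ctg$start, end = ctg$end),
    if (nrow(gap)) tibble::tibble(part_type = "N", component_id = NA_character_,
                                  orientation = NA_character_,
                                  start = gap$start, end = gap$end)
  )
  layout <- dplyr::arrange(
    dplyr::mutate(rows, scaffold_id = record$id, .before = 1), .data$start)
  comps <- tibble::tibble(
    id = comp_ids,
    seq = substring(record$seq, ctg$start + 1L, ctg$end),
    length = ctg$length)
  list(layout = layout, components = comps)
}

#' Read an AGP v2.1 file as a layout tibble
#'
#' `W` lines become components, `N`/`U` lines gaps; 1-based inclusive AGP
#' object coordinates are converted to 0-based half-open.
#'
#' @param path AGP file path.
#' @return Layout tibble as consumed by [apply_layout()].
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  purrr::map_dfr(f, function(x) {
    if (length(x) < 8) stop("malformed AGP row: ", paste(x, collapse = "\t"))
    type <- x[5]
    tibble::tibble(
      scaffold_id = x[1],
      part_type = if (type %in% c("N", "U")) "N" else "W",
      component_id = if (type %in% c("N", "U")) NA_character_ else x[6],
      orientation = if (type %in% c("N", "U")) NA_character_ else x[9],
      start = as.integer(x[2]) - 1L,
      end = as.integer(x[3]))
  })
}

#' Write a layout tibble as AGP v2.1
#' @param layout Layout tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(layout, path) {
  validate_layout(layout)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (sid in unique(layout$scaffold_id)) {
    l <- dplyr::arrange(layout[layout$scaffold_id == sid, ], .data$start)
    for (i in seq_len(nrow(l))) {
      r <- l[i, ]
      fields <- if (r$part_type == "N") {
        c(sid, r$start + 1L, r$end, i, "N", r$end - r$start, "scaffold",
          "yes", "paired-ends")
      } else {
        c(sid, r$start + 1L, r$end, i, "W", r$component_id, 1L,
          r$end - r$start, r$orientation)
      }
      writeLines(paste(fields, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write intervals as BED3
#' @param intervals Tibble with `seq_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("seq_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
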