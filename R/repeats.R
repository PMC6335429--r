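#' Parse a RepeatMasker .out annotation file
#'
#' Standard format: three header lines then whitespace-delimited rows.
#' 1-based inclusive query coordinates are converted to 0-based half-open;
#' the repeat class/family string is split on "/"; identity is
#' 100 - percent divergence.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return Tibble `seq_id`, `start`, `end`, `family`, `repeat_class`,
#'   `pct_divergence`, `identity`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 3) lines <- lines[-(1:3)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), family = character(),
                          repeat_class = character(),
                          pct_divergence = numeric(), identity = numeric()))
  }
  purrr::imap_dfr(strsplit(lines, "\\s+"), function(x, i) {
    if (length(x) < 11) stop("malformed RepeatMasker row at body line ", i)
    div <- suppressWarnings(as.numeric(x[2]))
    s <- suppressWarnings(as.integer(x[6]))
    e <- suppressWarnings(as.integer(x[7]))
    if (is.na(div) || is.na(s) || is.na(e) || e < s) {
      stop("malformed RepeatMasker row at body line ", i)
    }
    tibble::tibble(seq_id = x[5], start = s - 1L, end = e,
                   family = x[10], repeat_class = x[11],
                   pct_divergence = div, identity = 100 - div)
  })
}

#' Length distributions of long, well-conserved repeats by class
#'
#' Retains features with identity strictly above `min_identity` and length
#' strictly above `min_len`, grouped by repeat class (e.g. `LINE/L1`,
#' `LINE/RTE-BovB`, `Satellite/centr`).
#'
#' @param features Repeat tibble from [parse_repeatmasker_out()].
#' @param classes Character vector of repeat classes to profile.
#' @param min_len Minimum feature length (bp), exclusive.
#' @param min_identity Minimum identity (%), exclusive.
#' @return Named list of length vectors, one per requested class (empty
#'   vector, with a warning, for classes absent from the annotation).
#' @export
family_length_distribution <- function(features, classes, min_len = 2000,
                                       min_identity = 60) {
  f <- features[features$identity > min_identity &
                  (features$end - features$start) > min_len, , drop = FALSE]
  out <- lapply(classes, function(cl) {
    sel <- f[f$repeat_class == cl, ]
    if (!nrow(sel) && !any(features$repeat_class == cl)) {
      warning("repeat class ", cl, " not present in annotation")
    }
    sel$end - sel$start
  })
  rlang::set_names(out, classes)
}

#' Centromeric-repeat span and chromosome-end proximity
#'
#' For each chromosome: does any single centromeric feature span more than
#' `min_span` bp, and does any centromeric feature intersect the first or
#' last `window` bp of the chromosome? Acrocentric chromosomes show the
#' array near an end; sub-metacentric ones carry it internally at the
#' ancestral fusion junction.
#'
#' @param features Repeat tibble (will be restricted to `centr_class`).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window End window (bp).
#' @param min_span Span threshold (bp), exclusive.
#' @param centr_class Repeat class naming the centromeric satellite.
#' @param merged Measure spans on per-class merged arrays instead of single
#'   features?
#' @return Tibble `seq_id`, `has_centromeric_gt_min_span`,
#'   `centromere_near_end`, `max_span` (bp).
#' @export
centromere_proximity <- function(features, chrom_lengths, window = 100000,
                                 min_span = 5000,
                                 centr_class = "Satellite/centr",
                                 merged = FALSE) {
  cen <- features[features$repeat_class == centr_class, , drop = FALSE]
  purrr::imap_dfr(chrom_lengths, function(L, chrom) {
    if (is.na(L)) stop("no length for chromosome ", chrom)
    f <- cen[cen$seq_id == chrom, ]
    if (merged && nrow(f)) f <- merge_intervals(f)
    spans <- f$end - f$start
    near <- nrow(f) > 0 && any(f$start < window | f$end > L - window)
    tibble::tibble(seq_id = chrom,
                   has_centromeric_gt_min_span = any(spans > min_span),
                   centromere_near_end = near,
                   max_span = if (length(spans)) max(spans) else 0L)
  })
}

merge_intervals <- function(intervals) {
  iv <- dplyr::arrange(intervals, .data$seq_id, .data$start)
  out <- list()
  for (sid in unique(iv$seq_id)) {
    x <- iv[iv$seq_id == sid, ]
    cs <- x$start[1]; ce <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= ce) {
        ce <- max(ce, x$end[i])
      } else {
        out[[length(out) + 1]] <- tibble::tibble(seq_id = sid, start = cs, end = ce)
        cs <- x$start[i]; ce <- x$end[i]
      }
    }
    out[[length(out) + 1]] <- tibble::tibble(seq_id = sid, start = cs, end = ce)
  }
  dplyr::bind_rows(out)
}

# longest tandem run (in copies) of motif within seq, scanning each frame
max_tandem_copies <- function(seq, motif) {
  k <- nchar(motif)
  L <- nchar(seq)
  if (L < k) return(0L)
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(0L)
  best <- 1L
  run <- 1L
  for (i in seq_along(hits)[-1]) {
    if (hits[i] == hits[i - 1] + k) run <- run + 1L else run <- 1L
    best <- max(best, run)
  }
  best
}

#' Search chromosome ends for telomeric repeats
#'
#' Both strands (motif and its reverse complement) are scanned within the
#' first and last `end_window` bp; an end is called resolved when a tandem
#' run of at least `min_copies` motif copies is present.
#'
#' @param record One-row assembly tibble.
#' @param motif Telomeric motif (vertebrate default `TTAGGG`).
#' @param end_window Window at each end (bp).
#' @param min_copies Tandem copies required for a resolved call.
#' @return Tibble with rows `five_prime` and `three_prime`: `end`,
#'   `max_tandem_copies`, `resolved`.
#' @export
find_telomeric <- function(record, motif = "TTAGGG", end_window = 100000,
                           min_copies = 10) {
  stopifnot(nrow(record) == 1L)
  L <- record$length
  w5 <- substring(record$seq, 1, min(L, end_window))
  w3 <- substring(record$seq, max(1, L - end_window + 1), L)
  rc <- revcomp(motif)
  copies <- vapply(list(w5, w3), function(w) {
    max(max_tandem_copies(w, motif), max_tandem_copies(w, rc))
  }, integer(1))
  tibble::tibble(end = c("five_prime", "three_prime"),
                 max_tandem_copies = copies,
                 resolved = copies >= min_copies)
}

#' Fraction of unplaced-scaffold bases in a repeat class
#'
#' Features of the class are merged per scaffold (so overlapping annotations
#' are not double counted) and their bases divided by the summed scaffold
#' lengths.
#'
#' @param features Repeat tibble restricted (by you) to unplaced scaffolds.
#' @param scaffold_lengths Named vector of unplaced scaffold lengths (bp).
#' @param repeat_class Class to measure, e.g. `"Satellite/centr"`.
#' @return Fraction in [0, 1].
#' @export
unplaced_repeat_content <- function(features, scaffold_lengths,
                                    repeat_class = "Satellite/centr") {
  total <- sum(as.numeric(scaffold_lengths))
  if (total <= 0) stop("total scaffold length is zero")
  f <- features[features$repeat_class == repeat_class &
                  features$seq_id %in% names(scaffold_lengths), , drop = FALSE]
  if (!nrow(f)) return(0)
  m <- merge_intervals(f)
  sum(as.numeric(m$end - m$start)) / total
}
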