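mk_hit <- function(query_id = "q", chrom = "chr1", start = 100000,
                   end = 103000, strand = "+", ident = 95, len = 3000,
                   evalue = 1e-30, bitscore = 5000) {
  tibble::tibble(query_id = query_id, target_chrom = chrom,
                 pct_identity = ident, align_len = len, mismatch = 0,
                 gapopen = 0, q_start = 1, q_end = len,
                 target_start = start, target_end = end, strand = strand,
                 evalue = evalue, bitscore = bitscore)
}

test_that("extract_flanks obeys the window arithmetic and clipping", {
  rec <- assembly_tbl(s = paste(rep("A", 30000), collapse = ""))
  fl <- extract_flanks(rec, 10000, 10100)
  expect_equal(fl$start, c(7000, 10100))
  expect_equal(fl$end, c(10000, 13100))
  expect_false(any(fl$clipped))
  expect_equal(nchar(fl$seq), c(3000, 3000))

  fl2 <- extract_flanks(rec, 1000, 1100)
  expect_equal(fl2$start[1], 0)
  expect_true(fl2$clipped[1])
  expect_equal(nchar(fl2$seq[1]), 1000)

  nn <- assembly_tbl(s = paste(c(rep("N", 500), rep("A", 1000)),
                               collapse = ""))
  fl3 <- extract_flanks(nn, 500, 600, flank = 500)
  expect_false(fl3$alignable[1]) # left flank is all N
  expect_true(fl3$alignable[2])

  expect_error(extract_flanks(rec, 29000, 31000), "outside")
})

test_that("filter_hits applies the printed cutoffs strictly", {
  hits <- dplyr::bind_rows(
    mk_hit("keep", evalue = 1e-20, ident = 90, len = 2000),
    mk_hit("bad_e", evalue = 1e-5, ident = 99, len = 3000),
    mk_hit("bad_id", evalue = 1e-30, ident = 84, len = 2000),
    mk_hit("bad_id_edge", evalue = 1e-30, ident = 85, len = 2000),
    mk_hit("len_edge", evalue = 1e-30, ident = 90, len = 1000),
    mk_hit("bad_len", evalue = 1e-30, ident = 90, len = 999))
  kept <- filter_hits(hits)
  expect_setequal(kept$query_id, c("keep", "len_edge"))

  # monotone: relaxing any threshold never drops a previously kept hit
  for (args in list(list(max_evalue = 1e-5), list(min_identity = 60),
                    list(min_len = 100))) {
    relaxed <- do.call(filter_hits, c(list(hits), args))
    expect_true(all(kept$query_id %in% relaxed$query_id))
  }
})

test_that("classify_join applies the four conservation criteria", {
  L <- mk_hit(start = 100000, end = 103000)
  R <- mk_hit(start = 104500, end = 107500)
  v <- classify_join(L, R)
  expect_equal(v$status, "conserved")
  expect_equal(v$separation, 1500)

  expect_equal(classify_join(L, mk_hit(chrom = "chr2"))$status,
               "not_conserved")
  expect_equal(classify_join(L, mk_hit(strand = "-"))$status,
               "not_conserved")
  far <- mk_hit(start = 2103000, end = 2106000)
  expect_equal(classify_join(L, far)$status, "not_conserved")
  edge <- mk_hit(start = 103001, end = 1103000 + 2999)
  expect_equal(classify_join(L, mk_hit(start = 1100000, end = 1103000))$status,
               "conserved") # separation exactly 997000 <= 1 Mb

  # overlapping hits have zero separation
  expect_equal(classify_join(L, mk_hit(start = 102000, end = 105000))$separation,
               0)
  # unalignable when a flank has no surviving hit
  expect_equal(classify_join(L[0, ], R)$status, "unalignable")

  # symmetric under swapping flanks
  v2 <- classify_join(R, L)
  expect_equal(v2$status, v$status)
  expect_equal(v2$separation, v$separation)
})

test_that("near-tied best hits on different chromosomes degrade the verdict", {
  L <- dplyr::bind_rows(mk_hit(chrom = "chr1", bitscore = 5000),
                        mk_hit(chrom = "chr2", bitscore = 4900))
  R <- mk_hit(chrom = "chr1", start = 104000, end = 107000)
  expect_equal(classify_join(L, R)$status, "not_conserved")
  # a clearly better top hit keeps the normal rule
  L2 <- dplyr::bind_rows(mk_hit(chrom = "chr1", bitscore = 5000),
                         mk_hit(chrom = "chr2", bitscore = 2000))
  expect_equal(classify_join(L2, R)$status, "conserved")
})

test_that("blast tabular hits round-trip including minus-strand encoding", {
  hits <- dplyr::bind_rows(
    mk_hit("q1", start = 100, end = 600, strand = "+"),
    mk_hit("q2", start = 1000, end = 1500, strand = "-"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(hits, f)
  back <- read_blast_tab(f)
  expect_equal(back$strand, c("+", "-"))
  expect_equal(back$target_start, c(100, 1000))
  expect_equal(back$target_end, c(600, 1500))
  raw <- read.table(f, sep = "\t")
  expect_true(raw$V9[2] > raw$V10[2]) # minus strand stored start > end
})

test_that("assembly-wide verdicts recover injected mis-joins via synteny", {
  d <- default_sim()
  res <- validate_assembly_joins(d$def$joins, d$def$hit_tables)
  ov <- dplyr::left_join(res$overall,
                         d$def$joins[, c("join_id", "is_misjoin")],
                         by = "join_id")
  expect_true(all(ov$status[ov$is_misjoin] == "not_conserved"))
  expect_true(all(ov$status[!ov$is_misjoin] == "conserved"))
  # every join judged against every target genome
  expect_equal(nrow(res$verdicts),
               nrow(d$def$joins) * length(d$def$hit_tables))
})

test_that("one supporting genome is enough for overall conservation", {
  gaps <- tibble::tibble(join_id = "j1", left_query = "q_L",
                         right_query = "q_R")
  good <- dplyr::bind_rows(mk_hit("q_L"),
                           mk_hit("q_R", start = 104000, end = 107000))
  bad <- dplyr::bind_rows(mk_hit("q_L", chrom = "chrA"),
                          mk_hit("q_R", chrom = "chrB"))
  res <- validate_assembly_joins(gaps, list(goat = good, cattle = bad))
  expect_equal(res$overall$status, "conserved")
  res2 <- validate_assembly_joins(gaps, list(a = bad, b = bad))
  expect_equal(res2$overall$status, "not_conserved")
})
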