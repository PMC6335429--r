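flat_track <- function(seq_id = "s", len = 200000, depth = 40, step = 1000) {
  starts <- seq(0, len - 1, by = step)
  tibble::tibble(seq_id = seq_id, start = starts,
                 end = pmin(starts + step, len), depth = depth)
}

test_that("window_stats reports the centred window median and ratio", {
  cov <- flat_track(depth = 40)
  w <- window_stats(cov, "s", 100000)
  expect_equal(w$ratio, 1.0)
  expect_equal(w$window_median, 40)
  expect_equal(c(w$window_start, w$window_end), c(75000, 125000))
  expect_false(w$clipped)

  # a high-coverage island covering the window
  cov2 <- cov
  cov2$depth[cov2$start >= 70000 & cov2$end <= 130000] <- 120
  w2 <- window_stats(cov2, "s", 100000, genome_median = 40)
  expect_equal(w2$ratio, 3.0)

  # near the sequence end the window is truncated and flagged
  w3 <- window_stats(cov, "s", 10000)
  expect_true(w3$clipped)
  expect_equal(c(w3$window_start, w3$window_end), c(0, 35000))

  expect_error(window_stats(cov, "nope", 100), "no coverage")
  expect_error(window_stats(cov, "s", 1e9), "outside")
})

test_that("classify_break maps ratios to categories by the thresholds", {
  expect_equal(classify_break(1.0), "expected")
  expect_equal(classify_break(3.0), "high")
  expect_equal(classify_break(0.1), "low")
  expect_equal(classify_break(c(1.75, 0.25)), c("high", "low")) # boundaries
  expect_error(classify_break(1, high_threshold = 0.5))

  # monotonicity: raising the high threshold never creates new "high" calls
  set.seed(5)
  ratios <- runif(200, 0, 4)
  for (h in c(1.5, 2, 3)) {
    hi_low <- classify_break(ratios, high_threshold = h) == "high"
    hi_high <- classify_break(ratios, high_threshold = h + 0.5) == "high"
    expect_true(all(hi_high <= hi_low))
  }

  # ratio-based classification is invariant under depth scaling
  cov <- flat_track()
  r1 <- window_stats(cov, "s", 100000)$ratio
  cov$depth <- cov$depth * 13
  expect_equal(window_stats(cov, "s", 100000)$ratio, r1)
})

test_that("audit_breaks recovers the injected truth on simulated data", {
  d <- default_sim()
  calls <- audit_breaks(d$def$breaks, d$def$coverage)
  expect_equal(nrow(calls), nrow(d$def$breaks))
  truth <- d$def$truth$breaks$truth
  expect_equal(calls$verdict, truth)
  expect_true(all(calls$category[truth == "supported"] == "high"))
  expect_true(all(calls$verdict == "false_break") ==
                all(calls$category == "expected"))
  sm <- summarize_breaks(calls)
  expect_equal(sum(sm$n_breaks), nrow(calls))
  expect_equal(sum(sm$n_false) + sum(sm$n_supported), nrow(calls))
})

test_that("audit_breaks handles the degenerate inputs", {
  cov <- flat_track()
  empty <- tibble::tibble(scaffold_id = character(), position = numeric(),
                          source = character())
  expect_equal(nrow(audit_breaks(empty, cov)), 0L)
  three <- tibble::tibble(scaffold_id = "s",
                          position = c(60000, 100000, 140000),
                          source = "chicago")
  calls <- audit_breaks(three, cov)
  expect_equal(calls$verdict, rep("false_break", 3))
})

test_that("rejoining a single false break restores the parent component", {
  layout_after <- tibble::tibble(
    scaffold_id = "scf", part_type = "W",
    component_id = c("c1:0-4", "c1:4-9"), orientation = "+",
    start = c(0L, 4L), end = c(4L, 9L),
    source_id = "c1", source_start = c(0L, 4L), source_len = 9L)
  comps <- assembly_tbl(`c1:0-4` = "ACGT", `c1:4-9` = "TTTTT")
  calls <- tibble::tibble(scaffold_id = "scf", position = 4,
                          verdict = "false_break")
  out <- rejoin_false_breaks(layout_after, calls, comps)
  expect_equal(nrow(out$layout), 1L)
  expect_equal(out$layout$component_id, "c1")
  expect_equal(out$components$seq[out$components$id == "c1"], "ACGTTTTTT")

  # supported break: nothing changes
  calls$verdict <- "supported"
  out2 <- rejoin_false_breaks(layout_after, calls, comps)
  expect_equal(out2$layout, layout_after)
})

test_that("rejoin restores minus-orientation parents in their + sense", {
  # parent p = "AACCGGTT" placed "-": scaffold shows revcomp = AACCGGTT -> ...
  parent <- "AAACCGGG"
  scaffold_view <- revcomp(parent)          # CCCGGTTT
  left_part <- substring(scaffold_view, 1, 3)  # revcomp of parent tail
  right_part <- substring(scaffold_view, 4)
  layout_after <- tibble::tibble(
    scaffold_id = "scf", part_type = "W",
    component_id = c("p:5-8", "p:0-5"), orientation = "-",
    start = c(0L, 3L), end = c(3L, 8L),
    source_id = "p", source_start = c(5L, 0L), source_len = 8L)
  comps <- assembly_tbl("p:5-8" = revcomp(left_part),
                        "p:0-5" = revcomp(right_part))
  calls <- tibble::tibble(scaffold_id = "scf", position = 3,
                          verdict = "false_break")
  out <- rejoin_false_breaks(layout_after, calls, comps)
  expect_equal(out$layout$component_id, "p")
  expect_equal(out$components$seq[out$components$id == "p"], parent)
})

test_that("rejoining truth-labelled false breaks reconstructs the layout", {
  d <- default_sim()
  truth_calls <- dplyr::mutate(d$def$truth$breaks, verdict = truth)
  out <- rejoin_false_breaks(d$def$layout_after, truth_calls,
                             d$def$components_after)
  # scaffolds rebuilt from the corrected layout match the originals
  rebuilt <- apply_layout(out$layout, out$components)
  orig <- d$def$scaffolds
  expect_identical(rebuilt$seq[match(orig$id, rebuilt$id)], orig$seq)
  # per supported break one extra boundary remains vs the pre-break layout
  n_supported <- sum(truth_calls$verdict == "supported")
  expect_equal(nrow(out$layout), nrow(d$def$layout_before) + n_supported)
  # components of scaffolds without supported breaks regain original names
  sup_scaffolds <- unique(truth_calls$scaffold_id[truth_calls$verdict ==
                                                    "supported"])
  before <- d$def$layout_before
  clean <- setdiff(unique(before$scaffold_id), sup_scaffolds)
  for (sid in clean) {
    expect_setequal(out$layout$component_id[out$layout$scaffold_id == sid &
                                              out$layout$part_type == "W"],
                    before$component_id[before$scaffold_id == sid &
                                          before$part_type == "W"])
  }
})
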