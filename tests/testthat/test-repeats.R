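test_that("RepeatMasker .out round-trips through write and parse", {
  d <- default_sim()
  ledger <- d$sim$repeats
  f <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ledger, f)
  back <- parse_repeatmasker_out(f)
  cols <- c("seq_id", "start", "end", "family", "repeat_class",
            "pct_divergence", "identity")
  expect_equal(as.data.frame(back[, cols]), as.data.frame(ledger[, cols]))
})

test_that("parse_repeatmasker_out validates rows and handles empty bodies", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("h1", "h2", "", "bad row only"), f)
  expect_error(parse_repeatmasker_out(f), "line 1")
  writeLines(c("h1", "h2", ""), f)
  expect_equal(nrow(parse_repeatmasker_out(f)), 0L)
})

test_that("family length profiles apply identity and length cutoffs", {
  feats <- tibble::tibble(
    seq_id = "chr1", start = c(0, 5000, 20000, 40000),
    end = c(1500, 7500, 25000, 42600),
    family = "L1", repeat_class = "LINE/L1",
    pct_divergence = c(10, 10, 41, 45),
    identity = c(90, 90, 59, 55))
  out <- family_length_distribution(feats, "LINE/L1")
  expect_equal(out$`LINE/L1`, 2500) # short and low-identity copies excluded
  expect_warning(family_length_distribution(feats, "SINE/tRNA"),
                 "not present")
})

test_that("planted repeat arrays are recovered at their exact lengths", {
  d <- default_sim()
  classes <- c("LINE/L1", "LINE/RTE-BovB", "Satellite/centr")
  out <- family_length_distribution(d$sim$repeats, classes)
  ledger <- d$sim$repeats
  for (cl in classes) {
    planted <- ledger[ledger$repeat_class == cl &
                        ledger$identity > 60 &
                        (ledger$end - ledger$start) > 2000, ]
    expect_equal(sort(out[[cl]]), sort(planted$end - planted$start))
  }
  # the decayed LINE copy (identity 55) never appears
  expect_false(any(out$`LINE/L1` %in%
                     (ledger$end - ledger$start)[ledger$identity < 60]))
})

test_that("centromere proximity separates mid-chromosome from near-end arrays", {
  feats <- tibble::tibble(
    seq_id = c("c1", "c2"), start = c(50000, 15e6), end = c(58000, 15e6 + 4000),
    family = "SAT", repeat_class = "Satellite/centr",
    pct_divergence = 5, identity = 95)
  res <- centromere_proximity(feats, c(c1 = 30e6, c2 = 30e6))
  expect_true(res$has_centromeric_gt_min_span[res$seq_id == "c1"])
  expect_true(res$centromere_near_end[res$seq_id == "c1"])
  expect_false(res$has_centromeric_gt_min_span[res$seq_id == "c2"])
  expect_false(res$centromere_near_end[res$seq_id == "c2"])
  expect_error(centromere_proximity(feats, c(c1 = 30e6, c2 = NA)), "length")

  # simulated genome: chr1 is sub-metacentric (array at the fusion junction),
  # the others acrocentric (array near the start)
  d <- default_sim()
  lens <- rlang::set_names(d$sim$genome$length, d$sim$genome$id)
  sim_res <- centromere_proximity(d$sim$repeats, lens)
  expect_false(sim_res$centromere_near_end[sim_res$seq_id == "chr1"])
  expect_true(all(sim_res$centromere_near_end[sim_res$seq_id != "chr1"]))
  expect_equal(sum(sim_res$has_centromeric_gt_min_span), 2)
})

test_that("telomere search needs a tandem run and respects both strands", {
  plus <- assembly_tbl(s = paste0(strrep("TTAGGG", 50),
                                  strrep("A", 150000)))
  v <- find_telomeric(plus)
  expect_true(v$resolved[v$end == "five_prime"])
  expect_false(v$resolved[v$end == "three_prime"])

  minus <- assembly_tbl(s = paste0(strrep("A", 150000), strrep("CCCTAA", 20)))
  v2 <- find_telomeric(minus)
  expect_true(v2$resolved[v2$end == "three_prime"])

  none <- assembly_tbl(s = strrep("ACGT", 2000))
  expect_false(any(find_telomeric(none)$resolved))

  # scattered single motifs do not qualify
  scattered <- assembly_tbl(
    s = paste(rep(c("TTAGGG", strrep("C", 100)), 15), collapse = ""))
  expect_false(any(find_telomeric(scattered)$resolved))

  # reverse-complementing the record swaps the end verdicts
  rc <- assembly_tbl(s = revcomp(plus$seq))
  v3 <- find_telomeric(rc)
  expect_equal(v3$resolved[v3$end == "three_prime"],
               v$resolved[v$end == "five_prime"])
  expect_equal(v3$resolved[v3$end == "five_prime"],
               v$resolved[v$end == "three_prime"])
})

test_that("unplaced repeat content merges overlaps before dividing", {
  feats <- tibble::tibble(
    seq_id = "u1", start = c(0, 50), end = c(100, 150),
    family = "SAT", repeat_class = "Satellite/centr",
    pct_divergence = 5, identity = 95)
  expect_equal(unplaced_repeat_content(feats, c(u1 = 1000)), 0.15)
  one <- feats[1, ]; one$end <- 500
  expect_equal(unplaced_repeat_content(one, c(u1 = 1000)), 0.5)
  expect_equal(unplaced_repeat_content(feats[0, ], c(u1 = 1000)), 0)
  expect_error(unplaced_repeat_content(feats, c(u1 = 0)), "zero")
  # merging is idempotent: feeding duplicated features changes nothing
  expect_equal(unplaced_repeat_content(dplyr::bind_rows(feats, feats),
                                       c(u1 = 1000)), 0.15)
})
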