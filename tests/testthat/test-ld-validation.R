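two_snp_set <- function(gA, gB, scaffold = "s") {
  genotype_set(cbind(gA, gB),
               tibble::tibble(snp_id = c("s1", "s2"), scaffold_id = scaffold,
                              position = c(1000, 2000)))
}

test_that("genotype_set validates codes and sorts placements", {
  expect_error(two_snp_set(c(0, 3), c(0, 1)), "0/1/2")
  gs <- genotype_set(
    cbind(c(0, 1), c(2, 2), c(1, 0)),
    tibble::tibble(snp_id = c("a", "b", "c"), scaffold_id = "s",
                   position = c(300, 100, 200)))
  expect_equal(gs$snps$position, c(100, 200, 300))
  expect_equal(colnames(gs$geno), c("b", "c", "a"))
  expect_error(genotype_set(
    cbind(0, 1), tibble::tibble(snp_id = c("a", "b"), scaffold_id = "s",
                                position = c(5, 5))), "increasing")
})

test_that("pairwise association captures complete, absent and undefined LD", {
  # perfect coupling: every individual 0/0 or 2/2
  g <- two_snp_set(c(0, 0, 2, 2, 0, 2, 2, 0), c(0, 0, 2, 2, 0, 2, 2, 0))
  expect_equal(pairwise_association(g, 1, 2), 1.0)
  expect_equal(pairwise_association(g, "s1", "s1"), 1.0) # self
  # monomorphic column is undefined
  g2 <- two_snp_set(rep(0, 8), c(0, 1, 2, 0, 1, 2, 0, 1))
  expect_true(is.na(pairwise_association(g2, 1, 2)))

  # independent SNPs: association stays near zero at n = 500
  set.seed(21)
  small <- replicate(40, {
    gA <- rbinom(500, 2, 0.5); gB <- rbinom(500, 2, 0.5)
    pairwise_association(two_snp_set(gA, gB), 1, 2)
  })
  expect_gte(mean(small < 0.15), 0.95)

  # |r| is also available and bounded by |D'|
  g3 <- two_snp_set(c(0, 1, 2, 0, 1, 2, 2, 0), c(0, 1, 2, 1, 1, 2, 2, 0))
  expect_lte(pairwise_association(g3, 1, 2, measure = "r"),
             pairwise_association(g3, 1, 2) + 1e-9)
})

test_that("LD maps are non-decreasing with non-negative increments", {
  d <- default_sim()
  for (mode in c("r2decay", "malecot")) {
    lm <- build_ld_map(d$def$genotypes, "scaffold_restA", mode = mode)
    expect_true(all(lm$intervals$delta >= 0))
    expect_true(all(diff(lm$snps$ldu) >= -1e-12))
    expect_equal(lm$snps$ldu,
                 cumsum(c(0, lm$intervals$delta)))
  }
})

test_that("a single segregating haplotype pair gives a near-zero map", {
  cfg <- sim_config(seed = 31, recombination_between_blocks = 0,
                    ld_block_length = 1e9)
  sim <- simulate_genome(cfg)
  pop <- simulate_population(cfg, sim)
  lm <- build_ld_map(pop, "chr1", mode = "r2decay")
  expect_lt(max(lm$snps$ldu), 0.5)
  expect_lt(stats::median(lm$intervals$delta), 0.05)
})

test_that("concatenating independent chromosomes maximises the junction delta", {
  d <- default_sim()
  gs <- d$pop
  # fake scaffold: chr1 SNPs followed by chr2 SNPs with shifted positions
  sel <- gs$snps$scaffold_id %in% c("chr1", "chr2")
  meta <- gs$snps[sel, ]
  shift <- max(meta$position[meta$scaffold_id == "chr1"]) + 10000
  meta$position[meta$scaffold_id == "chr2"] <-
    meta$position[meta$scaffold_id == "chr2"] + shift
  n_chr1 <- sum(meta$scaffold_id == "chr1")
  meta$scaffold_id <- "fake"
  fake <- genotype_set(gs$geno[, sel, drop = FALSE], meta)
  lm <- build_ld_map(fake, "fake", mode = "r2decay")
  # the inter-chromosome interval carries the largest increment
  junction <- which.max(lm$intervals$delta)
  expect_equal(lm$intervals$left_pos[junction],
               max(lm$snps$position[lm$snps$position <= shift]))
})

test_that("reversing a scaffold mirrors the delta sequence exactly", {
  d <- default_sim()
  gs <- d$def$genotypes
  sel <- gs$snps$scaffold_id == "scaffold_restB"
  meta <- gs$snps[sel, ]
  L <- max(meta$position) + 500
  rev_meta <- tibble::tibble(snp_id = meta$snp_id, scaffold_id = "rev",
                             position = L - meta$position)
  fwd <- build_ld_map(gs, "scaffold_restB", mode = "r2decay")
  gs_rev <- genotype_set(gs$geno[, which(sel), drop = FALSE], rev_meta)
  rev <- build_ld_map(gs_rev, "rev", mode = "r2decay")
  expect_equal(rev$intervals$delta, rev(fwd$intervals$delta), tolerance = 1e-9)
})

test_that("derive_threshold implements the Tukey fence with an override", {
  expect_equal(derive_threshold(runif(30), rule = "constant"), 0.275)
  # all-equal calibration: fence equals the value, nothing strictly above
  d <- rep(0.1, 25)
  th <- derive_threshold(d)
  expect_equal(th, 0.1)
  expect_equal(sum(d > th), 0)
  # one gross outlier is flagged
  d2 <- c(rep(0.01, 100), 0.5)
  th2 <- derive_threshold(d2)
  q <- quantile(d2, c(0.25, 0.75), names = FALSE)
  expect_equal(th2, q[2] + 1.5 * (q[2] - q[1]))
  expect_true(0.5 > th2)
  expect_error(derive_threshold(runif(5)), "20")
})

test_that("detect_jumps flags exactly the intervals above theta", {
  lm <- toy_ld_map(c(0.01, 0.5, 0.02))
  j <- detect_jumps(lm, 0.275)
  expect_equal(j$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(j), 3)
  j0 <- detect_jumps(toy_ld_map(c(0.1, 0.2)), 0.275)
  expect_equal(sum(j0$flagged), 0)
  # threshold monotonicity: a higher theta never flags more
  set.seed(8)
  deltas <- rexp(50, 5)
  lmr <- toy_ld_map(deltas)
  for (th in c(0.1, 0.275, 0.5)) {
    f_lo <- detect_jumps(lmr, th)$flagged
    f_hi <- detect_jumps(lmr, th + 0.2)$flagged
    expect_true(all(f_hi <= f_lo))
  }
})

test_that("synthetic joins support the true pair in the true orientation", {
  d <- default_sim()
  gs <- d$def$genotypes
  tj <- test_synthetic_joins(gs, "scaffold_splitL", "scaffold_splitR")
  expect_equal(tj$status, "tested")
  expect_true(tj$supported)
  expect_equal(tj$best_orientation, "a+b+")
  expect_lt(tj$min_delta, 0.275)

  # scaffolds from different chromosomes are unsupported in all orientations
  tj2 <- test_synthetic_joins(gs, "scaffold_splitL", "scaffold_restB")
  expect_false(tj2$supported)
  expect_true(all(tj2$orientations$junction_delta >= 0.275))

  expect_error(test_synthetic_joins(gs, "scaffold_splitL", "scaffold_splitL"),
               "itself")
  few <- genotype_set(
    gs$geno[, 1:3, drop = FALSE],
    tibble::tibble(snp_id = c("a", "b", "c"),
                   scaffold_id = c("s1", "s2", "s2"),
                   position = c(100, 100, 200)))
  expect_equal(test_synthetic_joins(few, "s1", "s2")$status, "untestable")
})

test_that("combine_evidence requires both lines of evidence", {
  ld <- tibble::tibble(join_id = c("j1", "j2", "j3", "j4"),
                       flagged = c(TRUE, TRUE, FALSE, FALSE))
  sy <- tibble::tibble(join_id = c("j1", "j2", "j3", "j4"),
                       status = c("not_conserved", "conserved",
                                  "not_conserved", "conserved"))
  ce <- combine_evidence(ld, sy)
  expect_equal(ce$class, c("candidate", "watch", "watch", "clean"))
  expect_error(combine_evidence(ld[1:2, ], sy), "keyed")
})

test_that("the full evidence loop isolates the injected mis-join", {
  d <- default_sim()
  lm <- build_ld_map(d$def$genotypes, "scaffold_mj1", mode = "r2decay")
  jumps <- detect_jumps(lm, 0.275)
  # jump tables for the clean scaffolds too
  others <- setdiff(unique(d$def$joins$scaffold_id), "scaffold_mj1")
  for (sid in others) {
    n_snps <- sum(d$def$genotypes$snps$scaffold_id == sid)
    if (n_snps >= 3) {
      jumps <- dplyr::bind_rows(
        jumps, detect_jumps(build_ld_map(d$def$genotypes, sid,
                                         mode = "r2decay"), 0.275))
    }
  }
  flags <- ld_flags_for_joins(jumps, d$def$joins)
  synteny <- validate_assembly_joins(d$def$joins, d$def$hit_tables)$overall
  ce <- combine_evidence(flags, synteny)
  expect_equal(sort(ce$join_id[ce$class == "candidate"]),
               sort(d$def$truth$misjoins$join_id))
})
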