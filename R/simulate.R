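#' Configuration for the closed-loop assembly simulator
#'
#' Desk-scale defaults (three 400 kb chromosomes, 200 genotyped
#' individuals) keep every downstream stage testable in seconds while
#' preserving the statistical structure the auditing methods rely on:
#' block-wise LD decaying within chromosomes and absent across them,
#' elevated long-read depth over collapsed repeats, planted satellite /
#' LINE-like / telomeric arrays, and a rearranged related genome for
#' synteny checks.
#'
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @param n_chromosomes,chromosome_length Genome shape (bp).
#' @param snp_density SNPs per kb on the genotyping array.
#' @param ld_block_length Haplotype block length (bp).
#' @param recombination_between_blocks Probability a gamete re-draws its
#'   founder at a block boundary.
#' @param n_founders Founder haplotypes per block (2 gives complete
#'   within-block LD).
#' @param n_individuals Genotyped population size.
#' @param missing_rate Genotype missingness rate.
#' @param n_gaps_per_scaffold Contig joins (gaps) planted per scaffold.
#' @param gap_length N-run length of each planted gap (bp).
#' @param n_misjoins Cross-chromosome mis-joins to inject (0 or 1 at this
#'   scale).
#' @param n_false_breaks,n_true_breaks Scaffolder breaks to inject at
#'   flat-coverage sites (false) and over collapsed repeats (true).
#' @param collapsed_span Width of each collapsed-repeat region (bp); must
#'   exceed half the audit window for the depth ratio to register.
#' @param base_depth,collapsed_multiplier,noise_sd,coverage_step Coverage
#'   model: per-bin depth ~ Normal(base x multiplier, sd).
#' @param divergence Per-base divergence of the related genome.
#' @param telomere_copies Tandem telomeric motif copies planted at each
#'   chromosome end (0 = unresolved telomeres).
#' @param sv_n_per_category,sv_shared_fraction,sv_n_b_unique Structural
#'   difference sets: calls per category in set A, fraction of A planted
#'   also in B, and extra B-only calls per category.
#' @param flank Synteny flank length (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3,
                       chromosome_length = 400000,
                       snp_density = 0.3,
                       ld_block_length = 50000,
                       recombination_between_blocks = 0.1,
                       n_founders = 2,
                       n_individuals = 200,
                       missing_rate = 0.02,
                       n_gaps_per_scaffold = 3,
                       gap_length = 100,
                       n_misjoins = 1,
                       n_false_breaks = 10,
                       n_true_breaks = 5,
                       collapsed_span = 40000,
                       base_depth = 40,
                       collapsed_multiplier = 2.5,
                       noise_sd = 2,
                       coverage_step = 500,
                       divergence = 0.05,
                       invert_related = TRUE,
                       telomere_copies = 0,
                       sv_n_per_category = 8,
                       sv_shared_fraction = 0.125,
                       sv_n_b_unique = 6,
                       flank = 3000) {
  cfg <- as.list(environment())
  stopifnot(cfg$recombination_between_blocks >= 0,
            cfg$recombination_between_blocks <= 1,
            cfg$divergence >= 0, cfg$divergence <= 1,
            cfg$sv_shared_fraction >= 0, cfg$sv_shared_fraction <= 1,
            cfg$chromosome_length > 0)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.dna_alts <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  if (length(idx)) {
    v[idx] <- .dna_alts[cbind(match(v[idx], rownames(.dna_alts)),
                              sample.int(3, length(idx), replace = TRUE))]
  }
  paste(v, collapse = "")
}

# overwrite part of a sequence string in place (0-based half-open target)
splice_seq <- function(seq, start, insert) {
  paste0(substring(seq, 1, start), insert,
         substring(seq, start + nchar(insert) + 1))
}

tandem_array <- function(monomer, copies, per_copy_divergence) {
  paste(vapply(seq_len(copies), function(i) {
    mutate_dna(monomer, per_copy_divergence)
  }, character(1)), collapse = "")
}

#' Simulate a repeat-bearing genome and a rearranged related genome
#'
#' Chromosome 1 is built sub-metacentric (centromeric satellite array at
#' mid-chromosome, the ancestral fusion junction); the remaining
#' chromosomes are acrocentric (array within 100 kb of the start). Each
#' chromosome additionally carries LINE-like elements of varying length
#' and divergence, including one decayed copy below the 60% identity
#' cutoff. The related genome is the base genome with `divergence`
#' point mutations and every even-numbered chromosome inverted whole, so
#' within-chromosome colinearity is preserved while orientation flips
#' exercise strand handling.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (assembly tibble), `repeats` (planted-repeat
#'   ledger in [parse_repeatmasker_out()] form), `related` (assembly
#'   tibble), `chrom_map` (tibble `chrom`, `rel_chrom`, `strand`,
#'   `length`), `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$chromosome_length
  monomer <- random_dna(169)
  line_l1 <- random_dna(4000)
  line_bovb <- random_dna(3500)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  ledger <- list()
  genome <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ci) {
    s <- random_dna(L)
    feats <- list()
    plant <- function(s, start, piece, family, klass, div) {
      feats[[length(feats) + 1]] <<- tibble::tibble(
        seq_id = chroms[ci], start = start, end = start + nchar(piece),
        family = family, repeat_class = klass,
        pct_divergence = div, identity = 100 - div)
      splice_seq(s, start, piece)
    }
    # centromeric array: mid-chromosome on chr1, near the start elsewhere
    cen_copies <- if (ci <= 2) 39 else 23        # ~6.6 kb vs ~3.9 kb span
    cen_start <- if (ci == 1) floor(L / 2) else 20000
    cen <- tandem_array(monomer, cen_copies, 0.03)
    s <- plant(s, cen_start, cen, "SATB", "Satellite/centr", 3)
    # LINE copies: two young full-ish, one 5' truncated, one decayed
    for (k in 1:2) {
      st <- 60000 + 90000 * k + 7000 * ci
      div <- 8 + 4 * k
      s <- plant(s, st, mutate_dna(line_l1, div / 100), "L1_BT", "LINE/L1", div)
    }
    st <- 330000 + 5000 * ci
    s <- plant(s, st, mutate_dna(substring(line_bovb, 1000), 0.12),
               "BovB", "LINE/RTE-BovB", 12)
    s <- plant(s, 45000 + 3000 * ci,
               mutate_dna(substring(line_l1, 1, 2600), 0.45),
               "L1_BT", "LINE/L1", 45)
    if (config$telomere_copies > 0) {
      tel <- strrep("TTAGGG", config$telomere_copies)
      s <- plant(s, 0, tel, "(TTAGGG)n", "Simple_repeat", 0)
      s <- plant(s, L - nchar(tel), tel, "(TTAGGG)n", "Simple_repeat", 0)
    }
    ledger[[ci]] <<- dplyr::bind_rows(feats)
    tibble::tibble(id = chroms[ci], seq = s, length = nchar(s))
  })
  flip <- config$invert_related & seq_len(nrow(genome)) %% 2 == 0
  related <- purrr::map_dfr(seq_len(nrow(genome)), function(ci) {
    s <- mutate_dna(genome$seq[ci], config$divergence)
    if (flip[ci]) s <- revcomp(s)
    tibble::tibble(id = paste0("rel_", genome$id[ci]), seq = s,
                   length = nchar(s))
  })
  chrom_map <- tibble::tibble(
    chrom = genome$id, rel_chrom = related$id,
    strand = ifelse(flip, "-", "+"),
    length = genome$length)
  list(genome = genome, repeats = dplyr::bind_rows(ledger),
       related = related, chrom_map = chrom_map, config = config)
}

#' Simulate array genotypes with block-wise LD
#'
#' SNPs are placed at `snp_density` per kb; within each `ld_block_length`
#' block, haplotypes descend from `n_founders` founder haplotypes (complete
#' LD for the default two founders), gametes re-draw their founder at block
#' boundaries with probability `recombination_between_blocks`, and
#' chromosomes assort independently — so LD decays within chromosomes and
#' vanishes across them.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()] (for chromosome ids/lengths).
#' @return A [genotype_set()] with SNPs placed on the chromosomes.
#' @export
simulate_population <- function(config, sim) {
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  geno_parts <- list()
  meta_parts <- list()
  for (ci in seq_len(nrow(sim$genome))) {
    chrom <- sim$genome$id[ci]
    L <- sim$genome$length[ci]
    m <- max(3L, round(L / 1000 * config$snp_density))
    pos <- sort(sample(seq(5000L, L - 5000L), m))
    block <- floor(pos / config$ld_block_length)
    blocks <- unique(block)
    nf <- config$n_founders
    # founder haplotypes per block; two founders are kept complementary so
    # every SNP is polymorphic with allele frequency 1/2 in the founders
    founders <- matrix(0L, nf, m)
    for (b in blocks) {
      cols <- which(block == b)
      f1 <- sample(0:1, length(cols), replace = TRUE)
      founders[1, cols] <- f1
      if (nf >= 2) founders[2, cols] <- 1L - f1
      if (nf > 2) {
        for (f in 3:nf) founders[f, cols] <- sample(0:1, length(cols), TRUE)
      }
    }
    gamete <- function() {
      fidx <- integer(length(blocks))
      fidx[1] <- sample.int(nf, 1)
      for (bi in seq_along(blocks)[-1]) {
        fidx[bi] <- if (stats::runif(1) < config$recombination_between_blocks)
          sample.int(nf, 1) else fidx[bi - 1]
      }
      founders[cbind(fidx[match(block, blocks)], seq_len(m))]
    }
    g <- matrix(0L, n, m)
    for (ind in seq_len(n)) g[ind, ] <- gamete() + gamete()
    if (config$missing_rate > 0) {
      g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
    }
    geno_parts[[ci]] <- g
    meta_parts[[ci]] <- tibble::tibble(
      snp_id = sprintf("%s_snp%04d", chrom, seq_len(m)),
      scaffold_id = chrom, position = pos)
  }
  genotype_set(do.call(cbind, geno_parts), dplyr::bind_rows(meta_parts))
}

place_gaps <- function(scaffold_len, n_gaps, gap_length, forbidden, margin) {
  # sample gap starts away from ends, forbidden windows and each other
  ok_pos <- function(p) {
    all(p + gap_length <= forbidden$start | p >= forbidden$end)
  }
  out <- integer(0)
  tries <- 0
  while (length(out) < n_gaps && tries < 5000) {
    tries <- tries + 1
    p <- sample(seq(margin, scaffold_len - margin - gap_length), 1)
    if (ok_pos(p) && all(abs(p - out) > 2 * margin)) out <- c(out, p)
  }
  sort(out)
}

#' Inject assembly defects and emit every audit input plus its truth set
#'
#' Builds scaffolds from the simulated chromosomes: one cross-chromosome
#' mis-join (first half of chr1 joined to the second half of chr2 across a
#' gap), the two orphaned halves as their own scaffolds, and the last
#' chromosome split into two clean scaffolds (the true partners for
#' synthetic join testing). Every scaffold then receives planted contig
#' joins (gaps), a long-read coverage track with elevated depth over
#' collapsed-repeat regions, scaffolder breaks (false ones at flat
#' coverage, true ones over collapsed repeats), pre/post-break layouts,
#' SNP placements in scaffold coordinates, ideal flank-hit tables against
#' the related genome, and paired structural-difference call sets with a
#' planned shared fraction.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param pop Output of [simulate_population()].
#' @return List with `scaffolds`, `scaffold_map`, `genotypes` (SNPs in
#'   scaffold coordinates), `joins` (gap/join table with flank queries),
#'   `hit_tables` (named list per related genome), `coverage`, `breaks`,
#'   `layout_before`, `layout_after`, `components_after`, `sv` (list
#'   `set_a`, `set_b`), and `truth` (mis-joins, break verdicts, collapsed
#'   regions, SV share plan, split pair).
#' @export
inject_defects <- function(config, sim, pop) {
  set.seed(config$seed + 2L)
  flank_margin <- config$flank + 2000
  genome <- sim$genome
  nchr <- nrow(genome)
  stopifnot(nchr >= 3)
  gapN <- strrep("N", config$gap_length)
  L1 <- genome$length[1]; L2 <- genome$length[2]; L3 <- genome$length[nchr]
  c1 <- floor(L1 / 2); c2 <- floor(L2 / 2); c3 <- floor(L3 / 2)

  scaffold_map <- list(); scaff_seq <- list()
  if (config$n_misjoins > 0) {
    mj_seq <- paste0(substring(genome$seq[1], 1, c1), gapN,
                     substring(genome$seq[2], c2 + 1))
    scaff_seq[["scaffold_mj1"]] <- mj_seq
    scaffold_map[[length(scaffold_map) + 1]] <- tibble::tibble(
      scaffold_id = "scaffold_mj1",
      scf_start = c(0, c1 + config$gap_length),
      scf_end = c(c1, c1 + config$gap_length + (L2 - c2)),
      chrom = genome$id[1:2],
      chrom_start = c(0, c2), chrom_end = c(c1, L2), strand = "+")
    scaff_seq[["scaffold_restA"]] <- substring(genome$seq[1], c1 + 1)
    scaffold_map[[length(scaffold_map) + 1]] <- tibble::tibble(
      scaffold_id = "scaffold_restA", scf_start = 0, scf_end = L1 - c1,
      chrom = genome$id[1], chrom_start = c1, chrom_end = L1, strand = "+")
    scaff_seq[["scaffold_restB"]] <- substring(genome$seq[2], 1, c2)
    scaffold_map[[length(scaffold_map) + 1]] <- tibble::tibble(
      scaffold_id = "scaffold_restB", scf_start = 0, scf_end = c2,
      chrom = genome$id[2], chrom_start = 0, chrom_end = c2, strand = "+")
    middle <- seq_len(nchr)[-c(1, 2, nchr)]
  } else {
    middle <- seq_len(nchr)[-nchr]
  }
  for (ci in middle) {
    sid <- paste0("scaffold_", genome$id[ci])
    scaff_seq[[sid]] <- genome$seq[ci]
    scaffold_map[[length(scaffold_map) + 1]] <- tibble::tibble(
      scaffold_id = sid, scf_start = 0, scf_end = genome$length[ci],
      chrom = genome$id[ci], chrom_start = 0, chrom_end = genome$length[ci],
      strand = "+")
  }
  # last chromosome split in two: the true partners for synthetic joins
  scaff_seq[["scaffold_splitL"]] <- substring(genome$seq[nchr], 1, c3)
  scaff_seq[["scaffold_splitR"]] <- substring(genome$seq[nchr], c3 + 1)
  scaffold_map[[length(scaffold_map) + 1]] <- tibble::tibble(
    scaffold_id = c("scaffold_splitL", "scaffold_splitR"),
    scf_start = 0, scf_end = c(c3, L3 - c3),
    chrom = genome$id[nchr], chrom_start = c(0, c3), chrom_end = c(c3, L3),
    strand = "+")
  scaffold_map <- dplyr::bind_rows(scaffold_map)

  # plant contig joins (gaps) by replacing bases with N runs
  joins <- list()
  for (sid in names(scaff_seq)) {
    slen <- nchar(scaff_seq[[sid]])
    if (sid == "scaffold_mj1") {
      forbidden <- tibble::tibble(start = c1 - flank_margin,
                                  end = c1 + config$gap_length + flank_margin)
    } else {
      forbidden <- tibble::tibble(start = numeric(0), end = numeric(0))
    }
    n_g <- min(config$n_gaps_per_scaffold,
               max(0, floor((slen - 2 * flank_margin) / (3 * flank_margin))))
    gpos <- place_gaps(slen, n_g, config$gap_length, forbidden, flank_margin)
    for (p in gpos) {
      scaff_seq[[sid]] <- splice_seq(scaff_seq[[sid]], p, gapN)
      joins[[length(joins) + 1]] <- tibble::tibble(
        scaffold_id = sid, gap_start = p, gap_end = p + config$gap_length,
        is_misjoin = FALSE)
    }
    if (sid == "scaffold_mj1") {
      joins[[length(joins) + 1]] <- tibble::tibble(
        scaffold_id = sid, gap_start = c1, gap_end = c1 + config$gap_length,
        is_misjoin = TRUE)
    }
  }
  joins <- dplyr::arrange(dplyr::bind_rows(joins), .data$scaffold_id,
                          .data$gap_start)
  joins$join_id <- sprintf("join_%02d", seq_len(nrow(joins)))
  joins$left_query <- paste0(joins$join_id, "_L")
  joins$right_query <- paste0(joins$join_id, "_R")

  scaffolds <- tibble::tibble(id = names(scaff_seq),
                              seq = unname(unlist(scaff_seq)))
  scaffolds$length <- nchar(scaffolds$seq)

  # SNP placements carried from chromosome to scaffold coordinates
  snp_meta <- pop$snps
  placed <- purrr::pmap_dfr(scaffold_map, function(scaffold_id, scf_start,
                                                   scf_end, chrom,
                                                   chrom_start, chrom_end,
                                                   strand) {
    sel <- snp_meta$scaffold_id == chrom &
      snp_meta$position >= chrom_start & snp_meta$position < chrom_end
    out <- snp_meta[sel, ]
    if (!nrow(out)) return(NULL)
    tibble::tibble(snp_id = out$snp_id, scaffold_id = scaffold_id,
                   position = out$position - chrom_start + scf_start)
  })
  # drop SNPs that landed inside a planted gap
  in_gap <- purrr::map_lgl(seq_len(nrow(placed)), function(i) {
    g <- joins[joins$scaffold_id == placed$scaffold_id[i], ]
    any(placed$position[i] >= g$gap_start & placed$position[i] < g$gap_end)
  })
  placed <- placed[!in_gap, ]
  cols <- match(placed$snp_id, pop$snps$snp_id)
  genotypes <- genotype_set(pop$geno[, cols, drop = FALSE], placed)

  # ideal flank hits against the related genome
  flanks <- purrr::pmap_dfr(joins, function(scaffold_id, gap_start, gap_end,
                                            is_misjoin, join_id, left_query,
                                            right_query) {
    rec <- scaffolds[scaffolds$id == scaffold_id, ]
    fl <- extract_flanks(rec, gap_start, gap_end, flank = config$flank)
    fl$query_id <- c(left_query, right_query)
    fl$scaffold_id <- scaffold_id
    fl
  })
  hit_tables <- list(
    cattle_like = ideal_flank_hits(flanks, scaffold_map, sim$chrom_map,
                                   config$divergence),
    goat_like = ideal_flank_hits(flanks, scaffold_map, sim$chrom_map,
                                 config$divergence, target_suffix = "_g"))

  # coverage, collapsed repeats and scaffolder breaks
  step <- config$coverage_step
  window <- 50000
  collapsed <- list(); breaks <- list(); coverage <- list()
  big <- scaffolds[scaffolds$length >= 4 * window, ]
  n_true_left <- config$n_true_breaks
  n_false_left <- config$n_false_breaks
  for (si in seq_len(nrow(big))) {
    sid <- big$id[si]
    slen <- big$length[big$id == sid]
    n_t <- ceiling(n_true_left / (nrow(big) - si + 1))
    n_f <- ceiling(n_false_left / (nrow(big) - si + 1))
    n_true_left <- n_true_left - n_t
    n_false_left <- n_false_left - n_f
    col_iv <- list()
    tries <- 0
    while (length(col_iv) < n_t && tries < 2000) {
      tries <- tries + 1
      st <- sample(seq(window, slen - window - config$collapsed_span), 1)
      if (all(vapply(col_iv, function(iv)
        st + config$collapsed_span < iv[1] - window || st > iv[2] + window,
        logical(1)))) {
        col_iv[[length(col_iv) + 1]] <- c(st, st + config$collapsed_span)
      }
    }
    fpos <- numeric(0)
    tries <- 0
    while (length(fpos) < n_f && tries < 5000) {
      tries <- tries + 1
      p <- sample(seq(window, slen - window), 1)
      clear <- all(vapply(col_iv, function(iv)
        p < iv[1] - window / 2 - step || p > iv[2] + window / 2 + step,
        logical(1)))
      if (clear && all(abs(p - fpos) > 1000)) fpos <- c(fpos, p)
    }
    starts <- seq(0, slen - 1, by = step)
    ends <- pmin(starts + step, slen)
    depth <- stats::rnorm(length(starts), config$base_depth, config$noise_sd)
    for (iv in col_iv) {
      sel <- starts < iv[2] & ends > iv[1]
      depth[sel] <- stats::rnorm(sum(sel),
                                 config$base_depth * config$collapsed_multiplier,
                                 config$noise_sd)
    }
    coverage[[sid]] <- tibble::tibble(seq_id = sid, start = starts,
                                      end = ends, depth = pmax(depth, 0))
    if (length(col_iv)) {
      collapsed[[sid]] <- tibble::tibble(
        scaffold_id = sid,
        start = vapply(col_iv, `[`, numeric(1), 1),
        end = vapply(col_iv, `[`, numeric(1), 2))
      breaks[[paste0(sid, "_t")]] <- tibble::tibble(
        scaffold_id = sid,
        position = vapply(col_iv, function(iv) mean(iv), numeric(1)),
        truth = "supported")
    }
    if (length(fpos)) {
      breaks[[paste0(sid, "_f")]] <- tibble::tibble(
        scaffold_id = sid, position = fpos, truth = "false_break")
    }
  }
  breaks <- dplyr::bind_rows(breaks)
  if (!nrow(breaks)) {
    breaks <- tibble::tibble(scaffold_id = character(), position = numeric(),
                             truth = character())
  }
  breaks$position <- round(breaks$position)
  breaks$source <- sample(c("chicago", "hic"), nrow(breaks), replace = TRUE,
                          prob = c(0.9, 0.1))
  breaks <- dplyr::arrange(breaks, .data$scaffold_id, .data$position)
  coverage <- dplyr::bind_rows(coverage)

  # pre/post-break layouts with component provenance for rejoining
  layout_before <- list(); layout_after <- list(); comps_after <- list()
  applied <- character(0)
  for (sid in scaffolds$id) {
    dec <- decompose_scaffold(scaffolds[scaffolds$id == sid, ])
    lb <- dplyr::mutate(dec$layout,
                        source_id = .data$component_id,
                        source_start = 0L,
                        source_len = .data$end - .data$start)
    layout_before[[sid]] <- lb
    la <- lb
    comp <- dplyr::mutate(dec$components, source_id = .data$id)
    brks <- breaks[breaks$scaffold_id == sid, ]
    for (p in brks$position) {
      row <- which(la$part_type == "W" & la$start < p & la$end > p)
      if (length(row) != 1L) next # break fell on a gap or boundary; drop it
      applied <- c(applied, paste0(sid, ":", p))
      r <- la[row, ]
      local_p <- p - r$start + r$source_start
      part_name <- function(src, s, e, src_len) {
        if (s == 0 && e == src_len) src else sprintf("%s:%d-%d", src, s, e)
      }
      left_id <- part_name(r$source_id, r$source_start, local_p, r$source_len)
      right_id <- part_name(r$source_id, local_p,
                            r$source_start + (r$end - r$start), r$source_len)
      seq_full <- comp$seq[comp$id == r$component_id]
      cut <- p - r$start
      comp <- dplyr::bind_rows(
        comp[comp$id != r$component_id, ],
        tibble::tibble(id = c(left_id, right_id),
                       seq = c(substring(seq_full, 1, cut),
                               substring(seq_full, cut + 1)),
                       length = c(cut, nchar(seq_full) - cut),
                       source_id = r$source_id))
      la <- dplyr::bind_rows(
        la[-row, ],
        tibble::tibble(scaffold_id = sid, part_type = "W",
                       component_id = c(left_id, right_id),
                       orientation = "+",
                       start = c(r$start, p), end = c(p, r$end),
                       source_id = r$source_id,
                       source_start = c(r$source_start, local_p),
                       source_len = r$source_len))
      la <- dplyr::arrange(la, .data$start)
    }
    layout_after[[sid]] <- la
    comps_after[[sid]] <- comp
  }

  breaks <- breaks[paste0(breaks$scaffold_id, ":", breaks$position) %in%
                     applied, , drop = FALSE]

  sv <- simulate_sv_sets(config, genome$id[1], genome$length[1])

  truth <- list(
    misjoins = joins[joins$is_misjoin, c("join_id", "scaffold_id",
                                         "gap_start", "gap_end")],
    breaks = breaks[, c("scaffold_id", "position", "truth")],
    collapsed = dplyr::bind_rows(collapsed),
    sv_shared_planned = sv$shared_planned,
    split_pair = c("scaffold_splitL", "scaffold_splitR"))

  list(scaffolds = scaffolds, scaffold_map = scaffold_map,
       genotypes = genotypes, joins = joins, flanks = flanks,
       hit_tables = hit_tables, coverage = coverage,
       breaks = breaks[, c("scaffold_id", "position", "source")],
       layout_before = dplyr::bind_rows(layout_before),
       layout_after = dplyr::bind_rows(layout_after),
       components_after = dplyr::bind_rows(comps_after),
       sv = sv[c("set_a", "set_b")], truth = truth)
}

# ideal aligner: flank intervals are mapped through scaffold_map and
# chrom_map to the related genome and emitted as pre-normalised
# BLAST-tabular hits
ideal_flank_hits <- function(flanks, scaffold_map, chrom_map, divergence,
                             target_suffix = "") {
  purrr::map_dfr(seq_len(nrow(flanks)), function(i) {
    f <- flanks[i, ]
    if (!f$alignable) return(NULL)
    seg <- scaffold_map[scaffold_map$scaffold_id == f$scaffold_id &
                          scaffold_map$scf_start <= f$start &
                          scaffold_map$scf_end >= f$end, ]
    if (!nrow(seg)) return(NULL)
    seg <- seg[1, ]
    chrom_s <- f$start - seg$scf_start + seg$chrom_start
    chrom_e <- f$end - seg$scf_start + seg$chrom_start
    cm <- chrom_map[chrom_map$chrom == seg$chrom, ]
    if (cm$strand == "+") {
      ts <- chrom_s; te <- chrom_e; strand <- "+"
    } else {
      ts <- cm$length - chrom_e; te <- cm$length - chrom_s; strand <- "-"
    }
    len <- f$end - f$start
    ident <- 100 * (1 - divergence)
    mism <- round(len * divergence)
    tibble::tibble(
      query_id = f$query_id,
      target_chrom = paste0(cm$rel_chrom, target_suffix),
      pct_identity = ident, align_len = len, mismatch = mism, gapopen = 0,
      q_start = 1, q_end = len,
      target_start = ts + 1, target_end = te,
      strand = strand, evalue = 1e-50,
      bitscore = round(2 * len - 4 * mism))
  })
}

# paired structural-difference call sets with a planned shared fraction
simulate_sv_sets <- function(config, ref_id, ref_len) {
  ncat <- config$sv_n_per_category
  cats <- sv_categories
  total_a <- ncat * length(cats)
  mk <- function(n, cat, region_offset) {
    size <- round(exp(stats::runif(n, log(60), log(9000))))
    start <- sort(sample(seq(1000, ref_len - 20000, by = 1), n)) + region_offset
    width <- if (cat == "insertion") rep(1L, n) else size
    tibble::tibble(ref_seq_id = ref_id, start = start,
                   end = start + width, size = size, category = cat,
                   out_of_window = FALSE)
  }
  set_a <- purrr::map_dfr(cats, function(cc) mk(ncat, cc, 0))
  n_shared <- round(config$sv_shared_fraction * total_a)
  shared_idx <- sort(sample(seq_len(total_a), n_shared))
  shared_b <- set_a[shared_idx, ]
  shared_b$start <- shared_b$start + sample(-20:20, n_shared, replace = TRUE)
  shared_b$end <- shared_b$start +
    ifelse(shared_b$category == "insertion", 1L, shared_b$size)
  uniq_b <- purrr::map_dfr(cats, function(cc)
    mk(config$sv_n_b_unique, cc, 7))
  uniq_b$start <- uniq_b$start + 15000
  uniq_b$end <- uniq_b$start +
    ifelse(uniq_b$category == "insertion", 1L, uniq_b$size)
  # B-only records must not be matchable to A, or the planted shared count
  # would drift; drop any accidental same-category collision
  clash <- purrr::map_lgl(seq_len(nrow(uniq_b)), function(i) {
    u <- uniq_b[i, ]
    cand <- set_a[set_a$category == u$category, ]
    if (!nrow(cand)) return(FALSE)
    if (u$category == "insertion") {
      any(abs(cand$start - u$start) <= 100)
    } else {
      any(reciprocal_overlap(cand$start, cand$end, u$start, u$end) >= 0.5)
    }
  })
  uniq_b <- uniq_b[!clash, ]
  list(set_a = set_a,
       set_b = dplyr::bind_rows(shared_b, uniq_b),
       shared_planned = n_shared)
}

#' Write a coverage tibble as bedGraph
#' @param coverage Tibble `seq_id`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write repeat features in RepeatMasker .out layout
#' @param features Tibble as returned by [parse_repeatmasker_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(features, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat class/family",
    "")
  body <- sprintf("%5d %5.1f  0.0  0.0  %s %d %d (0) + %s %s 1 %d (0) %d",
                  1000L, features$pct_divergence, features$seq_id,
                  features$start + 1L, features$end, features$family,
                  features$repeat_class, features$end - features$start,
                  seq_len(nrow(features)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write hits as BLAST outfmt 6
#' @param hits Normalised hit tibble (as from [read_blast_tab()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  ts <- ifelse(hits$strand == "-", hits$target_end, hits$target_start)
  te <- ifelse(hits$strand == "-", hits$target_start, hits$target_end)
  df <- data.frame(hits$query_id, hits$target_chrom, hits$pct_identity,
                   hits$align_len, hits$mismatch, hits$gapopen,
                   hits$q_start, hits$q_end, ts, te,
                   format(hits$evalue, scientific = TRUE), hits$bitscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
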