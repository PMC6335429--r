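# shared fixtures; the default simulation is computed once per test run
# and reused across files

assembly_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), seq = unname(toupper(seqs)),
                 length = unname(nchar(seqs)))
}

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_genome(cfg)
    pop <- simulate_population(cfg, sim)
    def <- inject_defects(cfg, sim, pop)
    .sim_cache[[key]] <- list(cfg = cfg, sim = sim, pop = pop, def = def)
  }
  .sim_cache[[key]]
}

# independent regex-based gap scanner (oracle for find_gaps)
regex_gaps <- function(seq, min_run = 3) {
  m <- gregexpr(sprintf("N{%d,}", min_run), seq)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = as.integer(m) - 1L,
                 end = as.integer(m) - 1L + attr(m, "match.length"))
}

random_n_string <- function(len) {
  paste(sample(c("A", "C", "G", "T", "N", "N"), len, replace = TRUE,
               prob = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1)),
        collapse = "")
}

# brute-force N50: walk lengths in decreasing order until half covered
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= tot / 2) return(x)
  }
}

# exact rank-sum enumeration: distribution of W over all choose(n1+n2, n1)
# assignments of the observed ranks to sample one
exact_wilcox <- function(a, b, alternative = "greater") {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  p <- switch(alternative,
              greater = mean(w_all >= w_obs),
              less = mean(w_all <= w_obs),
              two.sided = min(1, 2 * min(mean(w_all >= w_obs),
                                         mean(w_all <= w_obs))))
  list(W = w_obs, p = p)
}

# minimal ld_map construction for threshold/jump unit tests
toy_ld_map <- function(deltas, positions = NULL, scaffold = "s") {
  m <- length(deltas) + 1
  if (is.null(positions)) positions <- seq_len(m) * 1000
  structure(list(
    scaffold_id = scaffold, mode = "toy",
    snps = tibble::tibble(snp_id = paste0("snp", seq_len(m)),
                          position = positions,
                          ldu = cumsum(c(0, deltas))),
    intervals = tibble::tibble(
      left_snp = paste0("snp", seq_len(m - 1)),
      right_snp = paste0("snp", seq(2, m)),
      left_pos = positions[-m], right_pos = positions[-1],
      d_bp = diff(positions), delta = deltas,
      estimable = TRUE),
    n_dropped = 0L), class = "ld_map")
}
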