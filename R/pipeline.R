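#' Run the full audit pipeline on one simulated assembly
#'
#' Generates a genome, population and defect set from `config`, runs every
#' auditing stage — coverage-based break classification, LDU-map jump
#' detection, synteny validation and evidence combination, and
#' structural-difference matching — and scores each stage against the
#' simulator's truth records.
#'
#' @param config A [sim_config()].
#' @param theta LD-jump threshold (LDU).
#' @param ld_mode LD map estimator passed to [build_ld_map()].
#' @return One-row tibble: `seed`, `n_false_breaks`, `n_true_breaks`,
#'   `break_sensitivity` (false breaks called false), `break_fpr` (true
#'   breaks mis-called false), `jump_localized` (a flagged LD jump within
#'   one interval of the injected mis-join junction),
#'   `misjoin_recovered` (mis-join candidates exactly match truth with no
#'   clean-join candidates), `sv_shared_error` (|recovered - planted|
#'   shared records).
#' @export
run_closed_loop <- function(config, theta = 0.275, ld_mode = "r2decay") {
  sim <- simulate_genome(config)
  pop <- simulate_population(config, sim)
  def <- inject_defects(config, sim, pop)

  calls <- audit_breaks(def$breaks, def$coverage)
  truth <- def$truth$breaks$truth
  sens <- mean(calls$verdict[truth == "false_break"] == "false_break")
  fpr <- mean(calls$verdict[truth == "supported"] == "false_break")

  jumps <- NULL
  for (sid in unique(def$genotypes$snps$scaffold_id)) {
    if (sum(def$genotypes$snps$scaffold_id == sid) < 3) next
    lm <- build_ld_map(def$genotypes, sid, mode = ld_mode)
    jumps <- dplyr::bind_rows(jumps, detect_jumps(lm, theta))
  }

  jump_localized <- NA
  if (nrow(def$truth$misjoins)) {
    mj <- def$truth$misjoins[1, ]
    jj <- jumps[jumps$scaffold_id == mj$scaffold_id, ]
    idx <- which(jj$left_pos <= mj$gap_start & jj$right_pos >= mj$gap_end)
    if (!length(idx)) idx <- which.min(abs((jj$left_pos + jj$right_pos) / 2 -
                                             mj$gap_start))
    near <- seq(max(1, idx - 1), min(nrow(jj), idx + 1))
    jump_localized <- any(jj$flagged[near])
  }

  flags <- ld_flags_for_joins(jumps, def$joins)
  synteny <- validate_assembly_joins(def$joins, def$hit_tables)$overall
  ce <- combine_evidence(flags, synteny)
  misjoin_recovered <- setequal(ce$join_id[ce$class == "candidate"],
                                def$truth$misjoins$join_id)

  m <- match_diffs(def$sv$set_a, def$sv$set_b)
  sv_err <- abs(m$partition$shared - def$truth$sv_shared_planned)

  tibble::tibble(
    seed = config$seed,
    n_false_breaks = sum(truth == "false_break"),
    n_true_breaks = sum(truth == "supported"),
    break_sensitivity = sens, break_fpr = fpr,
    jump_localized = jump_localized,
    misjoin_recovered = misjoin_recovered,
    sv_shared_error = sv_err)
}
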