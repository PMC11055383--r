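#' Run the full joint-deconvolution pipeline on a simulated experiment
#'
#' Chains the whole rescue-mode logic end to end: simulate an experiment,
#' match anonymous donors to hashtags by Phi score, build the joint
#' (rescued) assignment, reconstruct donor-specific genotypes, and
#' re-demultiplex against them as the sanity check.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written (correlations, pairs, score, joint assignment, flows, donor
#'   VCF, variant counts, refined assignment, concordance, and a
#'   machine-readable parameter log).
#' @param refine_cfg A `refinement_config`.
#' @param demux_cfg A `demux_config`.
#' @return List with `sim`, `match`, `joint`, `flows`, `rates`,
#'   `genotypes`, `refined`, `rescued_table`, `concordance`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         refine_cfg = refinement_config(),
                         demux_cfg = demux_config()) {
  sim <- simulate_experiment(cfg, dir = out_dir)
  match <- match_methods(sim$genetic, sim$hashing, cfg$n_donors)
  joint <- joint_assign(sim$hashing, sim$genetic, match)
  flows <- summarize_flows(sim$hashing, joint)
  rates <- rescue_rate(sim$hashing, joint)
  genotypes <- reconstruct_genotypes(sim$counts, joint, refine_cfg)
  refined <- assign_cells(sim$counts, genotypes, demux_cfg)
  rescued_table <- as_assignment_table(joint, "rescued")
  conc <- concordance(rescued_table, refined)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_match_result(match, out_dir)
    write_joint_assignment(joint, file.path(out_dir, "joint_assignment.csv"))
    utils::write.csv(flows, file.path(out_dir, "flows.csv"),
                     row.names = FALSE, quote = FALSE)
    write_donor_vcf(genotypes, file.path(out_dir, "donor_genotypes.vcf"))
    variant_count_table(genotypes, file.path(out_dir, "variant_counts.csv"))
    write_assignment_table(refined, file.path(out_dir, "refined_assignment.csv"))
    write_assignment_table(rescued_table, file.path(out_dir, "rescued_assignment.csv"))
    log <- list(mode = "pipeline", sim_config = unclass(cfg),
                refinement_config = unclass(refine_cfg),
                demux_config = unclass(demux_cfg),
                phi_score = match$phi_score,
                all_donors_matched = match$all_donors_matched,
                rescued_fraction = rates$rescued_fraction,
                singlet_fraction = rates$singlet_fraction,
                concordance = conc$concordance)
    jsonlite::write_json(log, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(sim = sim, match = match, joint = joint, flows = flows, rates = rates,
       genotypes = genotypes, refined = refined,
       rescued_table = rescued_table, concordance = conc)
}

req <- function(config, fields, mode) {
  miss <- fields[!vapply(fields, function(f)
    !is.null(config[[f]]), logical(1))]
  if (length(miss)) {
    stop(sprintf("mode '%s' requires field(s): %s", mode,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Run one pipeline stage from a configuration list
#'
#' File-level entry point behind the command-line interface.  `config` is
#' a flat list with a `mode` and mode-specific paths; every mode writes
#' its artifacts into `out_dir` plus a `params.json` parameter log that
#' fully determines the outputs.
#'
#' Modes and required fields:
#' \describe{
#'   \item{simulate}{`out_dir`; optional `sim` (a `sim_config`).}
#'   \item{match}{`genetic_csv`, `hashing_csv` (paths or vectors of
#'     paths), `n_donors`, `out_dir`.}
#'   \item{rescue}{`genetic_csv`, `hashing_csv`, `n_donors`, `out_dir`.}
#'   \item{refine}{`joint_csv`, `ad_mtx`, `dp_mtx`, `variants`,
#'     `barcodes`, `out_dir`; optional `refine` (a `refinement_config`).}
#'   \item{demux-ref}{`ad_mtx`, `dp_mtx`, `variants`, `barcodes`,
#'     `donor_vcf`, `out_dir`; optional `rescued_csv` for concordance and
#'     `demux` (a `demux_config`).}
#'   \item{summary}{`csv` (vector of paths), `out_dir`.}
#' }
#'
#' @param config Named list, see above.
#' @return The stage result, invisibly; artifacts on disk.
#' @export
run_stage <- function(config) {
  mode <- config$mode
  if (is.null(mode) ||
      !mode %in% c("simulate", "match", "rescue", "refine", "demux-ref", "summary")) {
    stop("config field 'mode' must be one of simulate/match/rescue/refine/demux-ref/summary",
         call. = FALSE)
  }
  req(config, "out_dir", mode)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(mode = mode)
  res <- switch(
    mode,
    "simulate" = {
      cfg <- config$sim %||% sim_config()
      log$sim_config <- unclass(cfg)
      simulate_experiment(cfg, dir = config$out_dir)
    },
    "match" = {
      req(config, c("genetic_csv", "hashing_csv", "n_donors"), mode)
      gts <- lapply(seq_along(config$genetic_csv), function(i)
        read_assignment_table(config$genetic_csv[i], paste0("genetic", i), "genetic"))
      hts <- lapply(seq_along(config$hashing_csv), function(i)
        read_assignment_table(config$hashing_csv[i], paste0("hashing", i), "hashing"))
      sel <- select_best_pair(gts, hts, config$n_donors)
      write_match_result(sel$best, config$out_dir)
      utils::write.csv(sel$ranking, file.path(config$out_dir, "pair_ranking.csv"),
                       row.names = FALSE, quote = FALSE)
      log$best_pair <- unname(sel$pair); log$phi_score <- sel$best$phi_score
      sel
    },
    "rescue" = {
      req(config, c("genetic_csv", "hashing_csv", "n_donors"), mode)
      gt <- read_assignment_table(config$genetic_csv[1], "genetic1", "genetic")
      ht <- read_assignment_table(config$hashing_csv[1], "hashing1", "hashing")
      m <- match_methods(gt, ht, config$n_donors)
      joint <- joint_assign(ht, gt, m)
      write_match_result(m, config$out_dir)
      write_joint_assignment(joint, file.path(config$out_dir, "joint_assignment.csv"))
      flows <- summarize_flows(ht, joint)
      utils::write.csv(flows, file.path(config$out_dir, "flows.csv"),
                       row.names = FALSE, quote = FALSE)
      rates <- rescue_rate(ht, joint)
      log$phi_score <- m$phi_score
      log$rescued_fraction <- rates$rescued_fraction
      log$singlet_fraction <- rates$singlet_fraction
      list(match = m, joint = joint, flows = flows, rates = rates)
    },
    "refine" = {
      req(config, c("joint_csv", "ad_mtx", "dp_mtx", "variants", "barcodes"), mode)
      joint <- read_joint_assignment(config$joint_csv)
      counts <- read_allele_counts(config$ad_mtx, config$dp_mtx,
                                   config$variants, config$barcodes)
      cfg <- config$refine %||% refinement_config()
      log$refinement_config <- unclass(cfg)
      genotypes <- reconstruct_genotypes(counts, joint, cfg)
      write_donor_vcf(genotypes, file.path(config$out_dir, "donor_genotypes.vcf"))
      variant_count_table(genotypes, file.path(config$out_dir, "variant_counts.csv"))
      genotypes
    },
    "demux-ref" = {
      req(config, c("ad_mtx", "dp_mtx", "variants", "barcodes", "donor_vcf"), mode)
      counts <- read_allele_counts(config$ad_mtx, config$dp_mtx,
                                   config$variants, config$barcodes)
      genotypes <- read_donor_vcf(config$donor_vcf)
      cfg <- config$demux %||% demux_config()
      log$demux_config <- unclass(cfg)
      refined <- assign_cells(counts, genotypes, cfg)
      write_assignment_table(refined, file.path(config$out_dir, "refined_assignment.csv"))
      out <- list(refined = refined)
      if (!is.null(config$rescued_csv)) {
        rescued <- read_assignment_table(config$rescued_csv, "rescued", "genetic")
        out$concordance <- concordance(rescued, refined)
        log$concordance <- out$concordance$concordance
        writeLines(format(out$concordance$concordance, digits = 15),
                   file.path(config$out_dir, "concordance.txt"))
      }
      out
    },
    "summary" = {
      req(config, "csv", mode)
      tabs <- lapply(seq_along(config$csv), function(i)
        read_assignment_table(config$csv[i],
                              config$method_names[i] %||% paste0("method", i),
                              config$families[i] %||% "hashing"))
      merged <- merge_summaries(tabs)
      tall <- classification_counts(tabs)
      utils::write.csv(merged, file.path(config$out_dir, "merged_assignments.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(tall, file.path(config$out_dir, "classification_counts.csv"),
                       row.names = FALSE, quote = FALSE)
      list(merged = merged, counts = tall)
    })
  log$inputs <- config[setdiff(names(config), c("mode", "sim", "refine", "demux"))]
  jsonlite::write_json(log, file.path(config$out_dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
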