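#' Default configuration for a full simulated concordance analysis
#'
#' One entry per simulated cancer type; each carries the cohort
#' specifications for the three modalities, the candidate-catalog
#' specification, per-modality FDR targets (5% everywhere, with a
#' per-cancer override slot for the stricter 1% copy-number control), the
#' marginal significance cutoff, permutation counts and per-stage seeds
#' derived from one master seed.
#'
#' @param seed master integer seed; every stage seed is derived from it.
#' @param cancers character vector of simulated cancer-type names.
#' @param n_genes,n_markers problem sizes per modality.
#' @param consistency cross-cohort direction-consistency rate planted by
#'   the generator.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, cancers = c("cancerA", "cancerB"),
                               n_genes = 2000, n_markers = 300,
                               consistency = 0.95) {
  cfg <- list(
    seed = as.integer(seed),
    cancers = cancers,
    fdr = list(expression = 0.05, methylation = 0.05, cna = 0.05),
    cna_fdr_override = list(),   # e.g. list(cancerB = 0.01)
    marginal_p_cut = 0.1,
    n_permutations = list(sam = 100, cna = 100),
    expression = list(n_genes = n_genes, n_cancer = 20, n_normal = 20,
                      frac_de = 0.1, effect_size = 2, noise_sd = 0.5,
                      consistency = consistency),
    methylation = list(n_genes = n_genes, n_cancer = 20, n_normal = 20,
                       frac_de = 0.1, effect_size = 0.2, noise_sd = 0.05,
                       consistency = consistency),
    cna = list(n_markers = n_markers, n_samples = 40, frac_alt = 0.2,
               amplitude = 0.8, noise_sd = 0.1, consistency = consistency,
               segment_length = 10, carrier_frac = 0.4),
    catalog = list(n_oncogenes = 15, n_tsgs = 15, frac_stability = 0.3,
                   mutation_rate = 0.3, shift = 2),
    stratify_gene = NULL  # default: first TSG of each cancer's catalog
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [default_run_config()]; missing
#'   fields fall back to the defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Deterministic per-stage seed stream
#'
#' Derives stage seeds from one master seed (kept below 2^31 so they remain
#' valid R integer seeds). Used by [run_full_analysis()] so that every
#' simulation and permutation stage draws from its own named stream.
#'
#' @param master master integer seed.
#' @param index stage index (any small integer; vectorized).
#' @return Integer seed(s).
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + 104729 * index) %% 2147483647)
}

format_rate <- function(report) {
  if (report$empty) return("-")
  sprintf("%.2f%% (%d)", 100 * report$agreement_rate, report$N)
}

analyze_expression_like <- function(pair, third_cohort, caller, stats_fun,
                                    fdr, p_cut) {
  calls1 <- caller(pair$cohort1, "d1")
  calls2 <- caller(pair$cohort2, "d2")
  stats1 <- stats_fun(pair$cohort1)
  stats2 <- stats_fun(pair$cohort2)
  merged <- merge_consistent(calls1, calls2)
  nonoverlap <- merged[merged$datasets != "A;B", , drop = FALSE]
  reports <- list(
    shared = shared_agreement(calls1, calls2),
    union = union_agreement(calls1, calls2, stats1, stats2),
    marginal = marginal_agreement(calls1, stats2, p_cut)
  )
  if (!is.null(third_cohort)) {
    calls3 <- caller(third_cohort, "d3")
    reports$third_dataset <- third_dataset_agreement(nonoverlap, calls3)
  }
  list(reports = reports, merged = merged,
       calls = list(calls1, calls2), stats = list(stats1, stats2))
}

run_one_cancer <- function(cancer, cfg, idx) {
  ex <- cfg$expression
  me <- cfg$methylation
  cn <- cfg$cna

  # --- expression ---
  espec <- cohort_spec(n_genes = ex$n_genes, n_cancer = ex$n_cancer,
                       n_normal = ex$n_normal, frac_de = ex$frac_de,
                       effect_size = ex$effect_size, noise_sd = ex$noise_sd,
                       consistency = ex$consistency,
                       seed = derive_seed(cfg$seed, 10 * idx + 1))
  epair <- generate_expression_pair(espec)
  third <- withr::with_seed(derive_seed(cfg$seed, 10 * idx + 2),
                            one_expression_cohort(espec, epair$truth,
                                                  "direction_cohort1", "c3"))
  sam_cfg <- function(seed_off) sam_config(n_permutations = cfg$n_permutations$sam,
                                           fdr_target = cfg$fdr$expression,
                                           seed = derive_seed(cfg$seed, 10 * idx + seed_off))
  expr_res <- analyze_expression_like(
    epair, third,
    caller = function(om, ds) call_de_genes(om, sam_cfg(3), dataset = ds),
    stats_fun = dataset_stats,
    fdr = cfg$fdr$expression, p_cut = cfg$marginal_p_cut
  )

  # --- methylation ---
  mspec <- cohort_spec(n_genes = me$n_genes, n_cancer = me$n_cancer,
                       n_normal = me$n_normal, frac_de = me$frac_de,
                       effect_size = me$effect_size, noise_sd = me$noise_sd,
                       consistency = me$consistency,
                       seed = derive_seed(cfg$seed, 10 * idx + 4))
  mpair <- generate_methylation_pair(mspec)
  mpair$cohort1 <- methylation_cohort_beta(mpair$cohort1)
  mpair$cohort2 <- methylation_cohort_beta(mpair$cohort2)
  meth_res <- analyze_expression_like(
    mpair, NULL,
    caller = function(om, ds) call_dm_genes(om, fdr_target = cfg$fdr$methylation,
                                            dataset = ds),
    stats_fun = dataset_stats,
    fdr = cfg$fdr$methylation, p_cut = cfg$marginal_p_cut
  )

  # --- copy number ---
  cna_fdr <- cfg$cna_fdr_override[[cancer]] %||% cfg$fdr$cna
  cspec <- cohort_spec(n_genes = cn$n_markers, n_cancer = cn$n_samples,
                       n_normal = 2, frac_de = cn$frac_alt,
                       effect_size = cn$amplitude, noise_sd = cn$noise_sd,
                       consistency = cn$consistency,
                       seed = derive_seed(cfg$seed, 10 * idx + 5))
  cpair <- generate_cna_profiles(cspec, segment_length = cn$segment_length,
                                 carrier_frac = cn$carrier_frac)
  cna1 <- call_cna_regions(cpair$cohort1, cpair$marker_map, fdr_target = cna_fdr,
                           n_permutations = cfg$n_permutations$cna,
                           seed = derive_seed(cfg$seed, 10 * idx + 6),
                           dataset = "d1")
  cna2 <- call_cna_regions(cpair$cohort2, cpair$marker_map, fdr_target = cna_fdr,
                           n_permutations = cfg$n_permutations$cna,
                           seed = derive_seed(cfg$seed, 10 * idx + 7),
                           dataset = "d2")
  cna_reports <- list(shared = shared_agreement(cna1$gene_calls, cna2$gene_calls))
  cna_merged <- merge_consistent(cna1$gene_calls, cna2$gene_calls)

  # --- catalog, mutations, stratified test ---
  cat_spec <- catalog_spec(n_oncogenes = cfg$catalog$n_oncogenes,
                           n_tsgs = cfg$catalog$n_tsgs,
                           frac_stability = cfg$catalog$frac_stability,
                           mutation_rate = cfg$catalog$mutation_rate)
  cm <- generate_catalog_and_mutations(cat_spec, epair$cohort1,
                                       cancer_type = cancer,
                                       shift = cfg$catalog$shift,
                                       seed = derive_seed(cfg$seed, 10 * idx + 8))
  strat_gene <- cfg$stratify_gene %||%
    cm$catalog$gene[cm$catalog$role == "TSG"][1]
  strat <- stratify_and_test(strat_gene, cm$expr, cm$mutations)
  reversal <- reversal_report(strat)

  merged_all <- dplyr::bind_rows(expr_res$merged, meth_res$merged, cna_merged)
  merged_all$cancer_type <- cancer

  list(cancer = cancer,
       reports = list(expression = expr_res$reports,
                      methylation = meth_res$reports,
                      cna = cna_reports),
       merged = merged_all,
       catalog = cm$catalog,
       stratified = list(gene = strat_gene, table = strat,
                         reversal = reversal),
       cna_fdr = cna_fdr)
}

#' Run the full simulated concordance analysis
#'
#' Orchestrates, for every configured cancer type: simulation of paired
#' cohorts for expression, methylation and copy number; differential
#' calling per cohort; the concordance report variants; consistency
#' merging; candidate-gene event counting with direction-bias tests and
#' background frequencies; and the mutation-stratified expression test.
#' All randomness flows from per-stage seeds derived from `config$seed`, so
#' two runs with the same configuration produce byte-identical report
#' bundles.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param outdir directory for the report bundle; created if needed. `NULL`
#'   skips writing.
#' @return Invisibly, a list with `concordance` (Table-1-style tibble),
#'   `events`, `bias_tests`, `background`, `stratified`, `merged`,
#'   `provenance`, and the per-cancer detail under `per_cancer`.
#' @export
run_full_analysis <- function(config = default_run_config(), outdir = NULL) {
  per_cancer <- lapply(seq_along(config$cancers), function(i)
    run_one_cancer(config$cancers[i], config, i))
  names(per_cancer) <- config$cancers

  # Table-1-style concordance table: one row per cancer, rate% (N) per cell
  conc_rows <- lapply(per_cancer, function(pc) {
    tibble::tibble(
      cancer_type = pc$cancer,
      expression_shared = format_rate(pc$reports$expression$shared),
      expression_union = format_rate(pc$reports$expression$union),
      expression_marginal = format_rate(pc$reports$expression$marginal),
      expression_third = format_rate(pc$reports$expression$third_dataset),
      methylation_shared = format_rate(pc$reports$methylation$shared),
      methylation_union = format_rate(pc$reports$methylation$union),
      cna_shared = format_rate(pc$reports$cna$shared),
      cna_fdr = pc$cna_fdr
    )
  })
  concordance <- dplyr::bind_rows(conc_rows)
  report_rows <- dplyr::bind_rows(lapply(per_cancer, function(pc) {
    dplyr::bind_rows(lapply(unlist(pc$reports, recursive = FALSE),
                            as.data.frame)) |>
      dplyr::mutate(cancer_type = pc$cancer, .before = 1)
  }))

  merged <- dplyr::bind_rows(lapply(per_cancer, `[[`, "merged"))
  catalog <- dplyr::distinct(dplyr::bind_rows(lapply(per_cancer, `[[`, "catalog")))
  events <- count_direction_events(merged, catalog)

  bias_tests <- list(
    oncogene_amplification = direction_bias_test(events, "oncogene", "amp", "cna"),
    tsg_deletion = direction_bias_test(events, "TSG", "del", "cna"),
    oncogene_up = direction_bias_test(events, "oncogene", "up", "expression"),
    nonstability_tsg_down = direction_bias_test(events, "TSG", "down",
                                                "expression", stability = FALSE),
    stability_tsg_up = direction_bias_test(events, "TSG", "up",
                                           "expression", stability = TRUE),
    nonstability_tsg_hyper = direction_bias_test(events, "TSG", "hyper",
                                                 "methylation", stability = FALSE),
    stability_tsg_hypo = direction_bias_test(events, "TSG", "hypo",
                                             "methylation", stability = TRUE)
  )
  background <- list(
    expression_up = background_frequency(merged, 1L, "expression"),
    methylation_hyper = background_frequency(merged, 1L, "methylation"),
    cna_amp = background_frequency(merged, 1L, "cna")
  )
  stratified <- lapply(per_cancer, function(pc) {
    list(cancer_type = pc$cancer, gene = pc$stratified$gene,
         strata = as.data.frame(pc$stratified$table),
         reversal = pc$stratified$reversal$reversal)
  })
  provenance <- list(
    package = "concordia",
    version = as.character(utils::packageVersion("concordia")),
    master_seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(seq_along(config$cancers),
             function(i) derive_seed(config$seed, 10 * i + 1:8)),
      config$cancers),
    config_hash = rlang::hash(config)
  )

  bundle <- list(concordance = concordance, reports = report_rows,
                 events = events, bias_tests = bias_tests,
                 background = background, stratified = stratified,
                 merged = merged, provenance = provenance,
                 per_cancer = per_cancer)
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  invisible(bundle)
}

bias_test_json <- function(bt) {
  lapply(bt, function(x) x[c("n_events", "n_favored", "frequency", "p_value")])
}

#' Write a report bundle to disk
#'
#' Emits `concordance_table.tsv`, `concordance_reports.tsv`, `events.tsv`,
#' `bias_tests.json`, `background_frequencies.json`,
#' `stratified_tests.json`, `merged_calls.tsv` and `provenance.json` under
#' `outdir`. Outputs contain no timestamps, so identical runs produce
#' byte-identical bundles.
#'
#' @param bundle result of [run_full_analysis()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(df, file.path(outdir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(bundle$concordance, "concordance_table.tsv")
  wt(bundle$reports, "concordance_reports.tsv")
  wt(bundle$events, "events.tsv")
  wt(bundle$merged, "merged_calls.tsv")
  wj <- function(x, f) jsonlite::write_json(x, file.path(outdir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, null = "null")
  wj(bias_test_json(bundle$bias_tests), "bias_tests.json")
  wj(bundle$background, "background_frequencies.json")
  wj(bundle$stratified, "stratified_tests.json")
  wj(bundle$provenance, "provenance.json")
  invisible(outdir)
}
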