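#!/usr/bin/env Rscript
# Simulate the study inputs: for each cancer type, two independent
# cancer-vs-normal cohorts per modality (expression, methylation beta,
# copy-number log2 ratios), a candidate oncogene/TSG catalog, and per-sample
# mutation classes. Truth sidecars are written next to every matrix so later
# scripts can check recovery against the planted signal.

source("analysis/00_config.R")

for (cancer in CANCERS) {
  specs <- cohort_specs(cfg, cancer)
  dir <- file.path(DATA_DIR, cancer)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  epair <- generate_expression_pair(specs$expression)
  write_scenario(epair, dir, "expression")

  mpair <- generate_methylation_pair(specs$methylation)
  mpair$cohort1 <- methylation_cohort_beta(mpair$cohort1)
  mpair$cohort2 <- methylation_cohort_beta(mpair$cohort2)
  write_scenario(mpair, dir, "methylation")

  cpair <- generate_cna_profiles(specs$cna,
                                 segment_length = cfg$cna$segment_length,
                                 carrier_frac = cfg$cna$carrier_frac)
  write_scenario(cpair, dir, "cna")
  write.table(cpair$marker_map, file.path(dir, "cna_marker_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat_spec <- catalog_spec(n_oncogenes = cfg$catalog$n_oncogenes,
                           n_tsgs = cfg$catalog$n_tsgs,
                           frac_stability = cfg$catalog$frac_stability,
                           mutation_rate = cfg$catalog$mutation_rate)
  cm <- generate_catalog_and_mutations(cat_spec, epair$cohort1,
                                       cancer_type = cancer,
                                       shift = cfg$catalog$shift,
                                       seed = specs$seed(8))
  write.table(cm$catalog, file.path(dir, "catalog.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$mutations, file.path(dir, "mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_omics_tsv(cm$expr, file.path(dir, "expression_mutstate.tsv"),
                  file.path(dir, "expression_mutstate_labels.tsv"))

  cat(sprintf("%s: %d genes (%d planted DE), %d methylation probes, %d markers (%d planted segments)\n",
              cancer, nrow(epair$cohort1$values), nrow(epair$truth),
              nrow(mpair$cohort1$values), nrow(cpair$cohort1$values),
              nrow(cpair$truth)))
}
cat("simulated inputs written under", DATA_DIR, "\n")
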