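#!/usr/bin/env Rscript
# Call differential genes per cohort: SAM-style permutation FDR for
# expression, t-test + Benjamini-Hochberg on beta-values for methylation,
# G-score regions with permutation q-values for copy number. One call table
# per (cancer, modality, cohort) lands under results/calls/.

source("analysis/00_config.R")

for (cancer in CANCERS) {
  specs <- cohort_specs(cfg, cancer)
  dir <- file.path(DATA_DIR, cancer)
  out <- file.path(CALLS_DIR, cancer)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cna_fdr <- cfg$cna_fdr_override[[cancer]]
  if (is.null(cna_fdr)) cna_fdr <- cfg$fdr$cna

  for (k in 1:2) {
    ds <- paste0("d", k)
    eom <- read_omics_tsv(file.path(dir, sprintf("expression_cohort%d.tsv", k)),
                          file.path(dir, sprintf("expression_cohort%d_labels.tsv", k)))
    de <- call_de_genes(eom, sam_config(n_permutations = cfg$n_permutations$sam,
                                        fdr_target = cfg$fdr$expression,
                                        seed = specs$seed(2 + k)), ds)
    write.table(de, file.path(out, sprintf("expression_%s.tsv", ds)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dataset_stats(eom), file.path(out, sprintf("expression_stats_%s.tsv", ds)),
                sep = "\t", quote = FALSE, row.names = FALSE)

    mom <- read_omics_tsv(file.path(dir, sprintf("methylation_cohort%d.tsv", k)),
                          file.path(dir, sprintf("methylation_cohort%d_labels.tsv", k)),
                          modality = "methylation")
    dm <- call_dm_genes(mom, fdr_target = cfg$fdr$methylation, dataset = ds)
    write.table(dm, file.path(out, sprintf("methylation_%s.tsv", ds)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dataset_stats(mom), file.path(out, sprintf("methylation_stats_%s.tsv", ds)),
                sep = "\t", quote = FALSE, row.names = FALSE)

    com <- read_omics_tsv(file.path(dir, sprintf("cna_cohort%d.tsv", k)),
                          file.path(dir, sprintf("cna_cohort%d_labels.tsv", k)),
                          modality = "cna")
    map <- read.delim(file.path(dir, "cna_marker_map.tsv"))
    cna <- call_cna_regions(com, map, fdr_target = cna_fdr,
                            n_permutations = cfg$n_permutations$cna,
                            seed = specs$seed(5 + k), dataset = ds)
    write.table(cna$gene_calls, file.path(out, sprintf("cna_%s.tsv", ds)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    reg <- cna$regions
    reg$genes <- vapply(reg$genes, paste, character(1), collapse = ";")
    write.table(reg, file.path(out, sprintf("cna_regions_%s.tsv", ds)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%s %s: %d DE, %d DM, %d CNA genes (CNA FDR %.0f%%)\n",
                cancer, ds, nrow(de), nrow(dm), nrow(cna$gene_calls),
                100 * cna_fdr))
  }
}
cat("call tables written under", CALLS_DIR, "\n")
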