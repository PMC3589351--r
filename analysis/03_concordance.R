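#!/usr/bin/env Rscript
# Cross-cohort directional concordance: for each cancer and modality, how
# often do the two cohorts' differential calls agree in direction, and how
# unlikely is that agreement under a fair coin? Writes the Table-1-style
# agreement table plus the merged consistent-direction call lists that the
# candidate-gene analysis consumes.

source("analysis/00_config.R")

read_calls <- function(cancer, modality, ds) {
  f <- file.path(CALLS_DIR, cancer, sprintf("%s_%s.tsv", modality, ds))
  tibble::as_tibble(read.delim(f))
}
read_stats <- function(cancer, modality, ds) {
  f <- file.path(CALLS_DIR, cancer, sprintf("%s_stats_%s.tsv", modality, ds))
  tibble::as_tibble(read.delim(f))
}

rows <- list(); merged_all <- list()
for (cancer in CANCERS) {
  for (modality in c("expression", "methylation", "cna")) {
    c1 <- read_calls(cancer, modality, "d1")
    c2 <- read_calls(cancer, modality, "d2")
    reports <- list(shared = shared_agreement(c1, c2))
    if (modality != "cna") {
      s1 <- read_stats(cancer, modality, "d1")
      s2 <- read_stats(cancer, modality, "d2")
      reports$union <- union_agreement(c1, c2, s1, s2)
      reports$marginal <- marginal_agreement(c1, s2, cfg$marginal_p_cut)
    }
    for (r in reports) {
      df <- as.data.frame(r)
      df$cancer_type <- cancer
      rows[[length(rows) + 1]] <- df
      print(r)
    }
    m <- merge_consistent(c1, c2)
    m$cancer_type <- cancer
    m$modality <- modality
    merged_all[[length(merged_all) + 1]] <- m
  }
}

conc <- dplyr::bind_rows(rows)
conc$rate_pct <- sprintf("%.2f%% (%d)", 100 * conc$agreement_rate, conc$N)
dir.create("results", showWarnings = FALSE)
write.table(conc, "results/concordance_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
merged <- dplyr::bind_rows(merged_all)
write.table(merged, "results/merged_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d merged consistent-direction calls across %d cancers\n",
            nrow(merged), length(CANCERS)))
cat("wrote results/concordance_table.tsv and results/merged_calls.tsv\n")
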