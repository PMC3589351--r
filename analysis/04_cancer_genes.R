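#!/usr/bin/env Rscript
# Candidate-gene direction events: do candidate oncogenes rise and candidate
# TSGs fall in their own cancer types once directions are consistency-merged?
# Counts events per (gene, cancer, modality), tests each class's directional
# bias against a fair coin, and compares candidate frequencies with the
# background frequencies of all retained differential genes.

source("analysis/00_config.R")

merged <- tibble::as_tibble(read.delim("results/merged_calls.tsv"))
catalogs <- dplyr::bind_rows(lapply(CANCERS, function(cc)
  tibble::as_tibble(read.delim(file.path(DATA_DIR, cc, "catalog.tsv")))))
catalogs <- dplyr::distinct(catalogs)

events <- count_direction_events(merged, catalogs)
write.table(events, "results/events.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tests <- list(
  oncogene_amplification = direction_bias_test(events, "oncogene", "amp", "cna"),
  oncogene_up = direction_bias_test(events, "oncogene", "up", "expression"),
  tsg_deletion = direction_bias_test(events, "TSG", "del", "cna"),
  nonstability_tsg_down = direction_bias_test(events, "TSG", "down",
                                              "expression", stability = FALSE),
  stability_tsg_up = direction_bias_test(events, "TSG", "up", "expression",
                                         stability = TRUE),
  nonstability_tsg_hyper = direction_bias_test(events, "TSG", "hyper",
                                               "methylation", stability = FALSE),
  stability_tsg_hypo = direction_bias_test(events, "TSG", "hypo",
                                           "methylation", stability = TRUE)
)
for (nm in names(tests)) {
  t <- tests[[nm]]
  if (t$empty) {
    cat(sprintf("%-24s no events\n", nm))
  } else {
    cat(sprintf("%-24s %2d of %2d events (%.0f%%), binomial p = %.3g\n",
                nm, t$n_favored, t$n_events, 100 * t$frequency, t$p_value))
  }
}
jsonlite::write_json(
  lapply(tests, function(x) x[c("n_events", "n_favored", "frequency", "p_value")]),
  "results/bias_tests.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

background <- list(
  expression_up = background_frequency(merged, 1L, "expression"),
  methylation_hyper = background_frequency(merged, 1L, "methylation"),
  cna_amp = background_frequency(merged, 1L, "cna")
)
jsonlite::write_json(background, "results/background_frequencies.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# both readings of the headline "average frequency" for the TSG deletions
ev_tsg_cna <- events[events$role == "TSG" & events$modality == "cna", ]
if (nrow(ev_tsg_cna)) {
  avg <- average_frequency(ev_tsg_cna, "del")
  cat(sprintf("TSG deletion frequency: pooled %.2f, per-cancer mean %.2f\n",
              avg$pooled, avg$mean_per_cancer))
}
cat("wrote results/events.tsv, results/bias_tests.json, results/background_frequencies.json\n")
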