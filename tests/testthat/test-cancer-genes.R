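toy_catalog <- function() {
  tibble::tibble(
    gene = c("ONC1", "ONC2", "TSG1", "TSG2", "TSG3"),
    role = c("oncogene", "oncogene", "TSG", "TSG", "TSG"),
    stability = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    cancer_types = c("lung;breast", "lung", "lung", "breast", "lung;breast")
  )
}

test_that("stability flags come from the annotation table", {
  cat <- toy_catalog()
  none <- classify_stability(cat, character(0))
  expect_false(any(none$stability))
  some <- classify_stability(cat, c("TSG2", "TSG3"))
  expect_equal(some$stability, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_warning(classify_stability(cat, "ONC1"), "oncogene")
  # data-frame annotations use the first column
  df <- classify_stability(cat, data.frame(gene = "TSG1"))
  expect_true(df$stability[df$gene == "TSG1"])
  # a synthetic catalog's planted fraction is recovered exactly
  expr <- generate_expression_pair(cohort_spec(n_genes = 60, seed = 5))$cohort1
  cm <- generate_catalog_and_mutations(catalog_spec(0, 20, 0.3, 0), expr, seed = 1)
  ann <- cm$catalog$gene[cm$catalog$stability]
  reflag <- classify_stability(cm$catalog, ann)
  expect_equal(mean(reflag$stability), 0.3)
})

test_that("catalogs may not assign both roles to one gene-cancer pair", {
  bad <- tibble::tibble(gene = c("X", "X"), role = c("oncogene", "TSG"),
                        stability = FALSE, cancer_types = c("lung", "lung"))
  merged <- toy_calls("X", 1)
  merged$cancer_type <- "lung"
  expect_error(count_direction_events(merged, bad), "both oncogene and TSG")
})

test_that("events count each (gene, cancer, modality) once, in any row order", {
  calls <- dplyr::bind_rows(
    toy_calls(c("ONC1", "TSG1", "other"), c(1, -1, 1)) |>
      dplyr::mutate(cancer_type = "lung"),
    toy_calls(c("ONC1", "TSG3"), c(-1, -1), modality = "cna") |>
      dplyr::mutate(cancer_type = "breast"),
    toy_calls("TSG3", -1, modality = "cna") |>
      dplyr::mutate(cancer_type = "lung")
  )
  ev <- count_direction_events(calls, toy_catalog())
  # "other" is no candidate; ONC2 has no call; ONC1 and TSG3 each have one
  # event per cancer type
  expect_equal(nrow(ev), 5)
  expect_setequal(ev$gene, c("ONC1", "TSG1", "TSG3"))
  expect_equal(sum(ev$gene == "TSG3"), 2)
  expect_equal(ev$direction[ev$gene == "ONC1" & ev$cancer_type == "lung"], "up")
  expect_equal(ev$direction[ev$gene == "ONC1" & ev$cancer_type == "breast"], "del")
  shuffled <- count_direction_events(calls[rev(seq_len(nrow(calls))), ], toy_catalog())
  expect_equal(dplyr::arrange(ev, gene, cancer_type, modality),
               dplyr::arrange(shuffled, gene, cancer_type, modality))
  # calls outside a candidate's own cancer types are not events
  off <- toy_calls("ONC2", 1)
  off$cancer_type <- "breast"  # ONC2 is a lung-only candidate
  expect_equal(nrow(count_direction_events(off, toy_catalog())), 0)
})

test_that("a constructed event table reproduces the 14/13 oncogene CNA split", {
  # 14 amplification events over 12 genes (two genes amplified in 2 cancers)
  # and 13 deletion events over 11 genes (two genes deleted in 2 cancers)
  amp_genes <- sprintf("OA%02d", 1:12)
  del_genes <- sprintf("OD%02d", 1:11)
  catalog <- tibble::tibble(
    gene = c(amp_genes, del_genes),
    role = "oncogene", stability = FALSE,
    cancer_types = c(rep("c1;c2", 2), rep("c1", 10),
                     rep("c1;c2", 2), rep("c1", 9))
  )
  calls <- tibble::tibble(
    gene = c(amp_genes, amp_genes[1:2], del_genes, del_genes[1:2]),
    direction = rep(c(1L, -1L), c(14, 13)),
    modality = "cna",
    cancer_type = c(rep("c1", 12), "c2", "c2", rep("c1", 11), "c2", "c2")
  )
  ev <- count_direction_events(calls, catalog)
  expect_equal(sum(ev$direction == "amp"), 14)
  expect_equal(sum(ev$direction == "del"), 13)
  expect_equal(length(unique(ev$gene[ev$direction == "amp"])), 12)
  expect_equal(length(unique(ev$gene[ev$direction == "del"])), 11)
  bias <- direction_bias_test(ev, "oncogene", "amp", "cna")
  expect_equal(bias$n_events, 27)
  expect_equal(bias$n_favored, 14)
  expect_equal(bias$p_value, 0.5)
})

test_that("an all-deletion TSG class gives the extreme binomial tail", {
  genes <- sprintf("T%02d", 1:16)
  catalog <- tibble::tibble(gene = genes, role = "TSG", stability = FALSE,
                            cancer_types = c(rep("c1;c2", 7), rep("c1", 9)))
  calls <- tibble::tibble(
    gene = c(genes, genes[1:7]), direction = -1L, modality = "cna",
    cancer_type = rep(c("c1", "c2"), c(16, 7))
  )
  ev <- count_direction_events(calls, catalog)
  bias <- direction_bias_test(ev, "TSG", "del", "cna")
  expect_equal(bias$n_events, 23)
  expect_equal(bias$frequency, 1)
  expect_equal(bias$p_value, 0.5^23)
  expect_equal(length(unique(ev$gene)), 16)
  # opposite direction has zero frequency; the two frequencies sum to one
  amp <- direction_bias_test(ev, "TSG", "amp", "cna")
  expect_equal(bias$frequency + amp$frequency, 1)
  # and an empty class is flagged rather than tested
  onc <- direction_bias_test(ev, "oncogene", "amp", "cna")
  expect_true(onc$empty)
  expect_true(is.na(onc$p_value))
})

test_that("planted class bias is recovered within the exact binomial interval", {
  set.seed(11)
  n_ev <- 60
  beta <- 0.8
  dirs <- ifelse(runif(n_ev) < beta, "down", "up")
  ev <- tibble::tibble(gene = sprintf("T%03d", 1:n_ev), cancer_type = "c1",
                       modality = "expression", direction = dirs,
                       role = "TSG", stability = FALSE)
  bias <- direction_bias_test(ev, "TSG", "down", "expression", stability = FALSE)
  expect_gte(bias$n_favored, qbinom(0.025, n_ev, beta))
  expect_lte(bias$n_favored, qbinom(0.975, n_ev, beta))
})

test_that("background and average frequencies are computed per cancer", {
  merged <- tibble::tibble(
    gene = sprintf("g%d", 1:10),
    direction = c(1, 1, 1, -1, -1, 1, -1, -1, -1, -1),
    modality = "expression",
    cancer_type = rep(c("c1", "c2"), each = 5)
  )
  bg <- background_frequency(merged, 1L, "expression")
  expect_equal(bg$frequency[bg$cancer_type == "c1"], 3 / 5)
  expect_equal(bg$frequency[bg$cancer_type == "c2"], 1 / 5)

  ev <- tibble::tibble(gene = sprintf("g%d", 1:6),
                       cancer_type = rep(c("c1", "c2"), c(4, 2)),
                       modality = "cna",
                       direction = c("del", "del", "del", "amp", "del", "amp"),
                       role = "TSG", stability = FALSE)
  avg <- average_frequency(ev, "del")
  expect_equal(avg$pooled, 4 / 6)
  expect_equal(avg$mean_per_cancer, mean(c(3 / 4, 1 / 2)))
})
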