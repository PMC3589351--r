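test_that("identical specs generate identical data", {
  spec <- cohort_spec(n_genes = 100, seed = 42)
  a <- generate_expression_pair(spec)
  b <- generate_expression_pair(spec)
  expect_identical(a, b)
  m1 <- generate_methylation_pair(cohort_spec(n_genes = 50, effect_size = 0.2,
                                              noise_sd = 0.05, seed = 8))
  m2 <- generate_methylation_pair(cohort_spec(n_genes = 50, effect_size = 0.2,
                                              noise_sd = 0.05, seed = 8))
  expect_identical(m1, m2)
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_cancer = 1), ">= 2")
  expect_error(cohort_spec(frac_de = 1.2), "frac_de")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(n_genes = 50, frac_de = 0.001), "planted")
  expect_error(catalog_spec(n_oncogenes = -1), ">= 0")
  expect_error(catalog_spec(mutation_rate = 2), "mutation_rate")
})

test_that("consistency = 1 forces agreement; frac_de = 0 plants nothing", {
  pair <- generate_expression_pair(cohort_spec(n_genes = 300, frac_de = 0.2,
                                               consistency = 1, seed = 2))
  expect_true(all(pair$truth$consistent))
  expect_equal(pair$truth$direction_cohort1, pair$truth$direction_cohort2)

  null_pair <- generate_expression_pair(cohort_spec(n_genes = 300, frac_de = 0,
                                                    seed = 3))
  expect_equal(nrow(null_pair$truth), 0)
  # group means differ only by noise
  om <- null_pair$cohort1
  gap <- rowMeans(om$values[, om$groups == "cancer"]) -
    rowMeans(om$values[, om$groups == "normal"])
  expect_lt(max(abs(gap)), 5 * 0.5 / sqrt(10))
})

test_that("planted cross-cohort agreement lands in the exact binomial interval", {
  pair <- generate_expression_pair(cohort_spec(n_genes = 2000, frac_de = 0.1,
                                               consistency = 0.95, seed = 7))
  # recount signs directly from the stored truth table
  n <- nrow(pair$truth)
  m <- sum(pair$truth$direction_cohort1 == pair$truth$direction_cohort2)
  expect_equal(n, 200)
  expect_gte(m, qbinom(0.025, n, 0.95))
  expect_lte(m, qbinom(0.975, n, 0.95))
  # the planted shifts really are +-effect_size in the group means
  om <- pair$cohort1
  gap <- rowMeans(om$values[, om$groups == "cancer"]) -
    rowMeans(om$values[, om$groups == "normal"])
  planted <- match(pair$truth$gene, rownames(om$values))
  expect_equal(unname(sign(gap[planted])), pair$truth$direction_cohort1)
})

test_that("methylation generator respects the beta identity and planted shifts", {
  spec <- cohort_spec(n_genes = 500, n_cancer = 30, n_normal = 30,
                      frac_de = 0.1, effect_size = 0.2, noise_sd = 0.05,
                      consistency = 1, seed = 19)
  mp <- generate_methylation_pair(spec)
  co <- mp$cohort1
  expect_true(all(co$U >= 0) && all(co$M >= 0))
  beta <- compute_beta(co$U, co$M)
  expect_true(all(beta >= 0 & beta < 1))
  # an all-methylated probe still has beta < 1
  expect_lt(max(compute_beta(0, co$M)), 1)
  # planted hyper probes: recovered mean beta shift within 3 standard errors
  hyper <- mp$truth$gene[mp$truth$direction_cohort1 == 1]
  gap <- rowMeans(beta[hyper, co$groups == "cancer", drop = FALSE]) -
    rowMeans(beta[hyper, co$groups == "normal", drop = FALSE])
  se <- 0.05 * sqrt(1 / 30 + 1 / 30)
  expect_true(all(abs(gap - 0.2) < 3 * se))
  # null methylation generator: no systematic group difference
  null_mp <- generate_methylation_pair(cohort_spec(n_genes = 200, frac_de = 0,
                                                   effect_size = 0.2,
                                                   noise_sd = 0.05, seed = 5))
  b0 <- methylation_cohort_beta(null_mp$cohort1)
  gap0 <- rowMeans(b0$values[, b0$groups == "cancer"]) -
    rowMeans(b0$values[, b0$groups == "normal"])
  expect_lt(max(abs(gap0)), 5 * se)
})

test_that("planted CNA segments have G close to frequency x amplitude", {
  spec <- cohort_spec(n_genes = 300, n_cancer = 50, n_normal = 2,
                      frac_de = 0.1, effect_size = 0.8, noise_sd = 0.05,
                      consistency = 1, seed = 27)
  cna <- generate_cna_profiles(spec, segment_length = 10, carrier_frac = 0.4)
  g_amp <- gscore(cna$cohort1$values, "amplification")
  g_del <- gscore(cna$cohort1$values, "deletion")
  for (i in seq_len(nrow(cna$truth))) {
    rows <- (cna$truth$marker_start[i] + 1):cna$truth$marker_end[i]
    g <- if (cna$truth$direction_cohort1[i] > 0) g_amp else g_del
    # f x a computed from the generated matrix directly
    vals <- cna$cohort1$values[rows, , drop = FALSE]
    sgn <- cna$truth$direction_cohort1[i]
    direct <- unname(rowSums(sgn * vals * (sgn * vals > 0.1)) / ncol(vals))
    expect_equal(g[rows], direct)
    expect_equal(mean(g[rows]), 0.32, tolerance = 0.1)
  }
  # a segment amplified in every sample at +1 dominates the G landscape
  om <- cna$cohort1
  om$values[1:10, ] <- om$values[1:10, ] * 0 + 1
  g <- gscore(om$values, "amplification")
  expect_equal(which.max(g), as.integer(which.max(g[1:10])))
  expect_true(all(g[1:10] >= max(g[-(1:10)])))
})

test_that("catalog and mutation generator honors its spec", {
  expr <- generate_expression_pair(cohort_spec(n_genes = 100, seed = 1))$cohort1
  # mutation_rate = 0: everyone wild type
  cm0 <- generate_catalog_and_mutations(catalog_spec(5, 5, 0.5, 0), expr, seed = 2)
  expect_true(all(cm0$mutations$mclass == "wild_type"))
  expect_identical(cm0$expr$values, expr$values)
  # frac_stability = 1: every TSG flagged
  cm1 <- generate_catalog_and_mutations(catalog_spec(5, 5, 1, 0.3), expr, seed = 2)
  expect_true(all(cm1$catalog$stability[cm1$catalog$role == "TSG"]))
  expect_false(any(cm1$catalog$stability[cm1$catalog$role == "oncogene"]))
  # fraction flagged is exact, not sampled
  cm3 <- generate_catalog_and_mutations(catalog_spec(0, 10, 0.3, 0.3), expr, seed = 4)
  expect_equal(sum(cm3$catalog$stability), 3)
})

test_that("activating strata planted by the generator are detectable", {
  expr <- generate_expression_pair(cohort_spec(n_genes = 200, n_cancer = 60,
                                               frac_de = 0, seed = 3))$cohort1
  cm <- generate_catalog_and_mutations(catalog_spec(5, 5, 0.5, 0.5), expr,
                                       shift = 2, seed = 6)
  g <- cm$catalog$gene[1]
  res <- stratify_and_test(g, cm$expr, cm$mutations)
  act <- res[res$mclass == "activating", ]
  expect_true(act$tested)
  expect_equal(act$direction, 1L)
  expect_lt(act$p_value, 0.05)
})

test_that("scenarios round-trip through TSV with truth sidecars", {
  dir <- withr::local_tempdir()
  pair <- generate_expression_pair(cohort_spec(n_genes = 40, seed = 4))
  write_scenario(pair, dir, "expr")
  om <- read_omics_tsv(file.path(dir, "expr_cohort1.tsv"),
                       file.path(dir, "expr_cohort1_labels.tsv"))
  expect_equal(om$values, pair$cohort1$values)
  expect_equal(om$groups, pair$cohort1$groups)
  truth <- read.delim(file.path(dir, "expr_truth.tsv"))
  expect_equal(truth$gene, pair$truth$gene)
  expect_equal(truth$direction_cohort2, pair$truth$direction_cohort2)
})
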