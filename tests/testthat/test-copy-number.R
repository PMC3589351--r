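test_that("G-score is frequency times mean exceeding amplitude", {
  # every sample amplified at +1.0
  expect_equal(gscore(rep(1, 10)), 1)
  # nobody over the threshold
  expect_equal(gscore(rep(0.05, 10)), 0)
  # 4 of 10 samples at +0.8: G = 0.4 * 0.8
  expect_equal(gscore(c(rep(0.8, 4), rep(0, 6))), 0.32)
  # deletions are scored on negated values
  expect_equal(gscore(c(rep(-0.8, 4), rep(0, 6)), "deletion"), 0.32)
  expect_error(gscore(rep(1, 5), threshold = 0), "threshold")
})

test_that("amplification analysis of X equals deletion analysis of -X", {
  spec <- cohort_spec(n_genes = 120, n_cancer = 30, n_normal = 2,
                      frac_de = 0.25, effect_size = 0.8, noise_sd = 0.1,
                      consistency = 1, seed = 9)
  cna <- generate_cna_profiles(spec, segment_length = 10)
  om <- cna$cohort1
  neg <- omics_matrix(-om$values, as.character(om$groups), "cna")
  r1 <- call_cna_regions(om, cna$marker_map, n_permutations = 40, seed = 5)
  r2 <- call_cna_regions(neg, cna$marker_map, n_permutations = 40, seed = 5)
  amp1 <- r1$regions[r1$regions$type == "amplification", ]
  del2 <- r2$regions[r2$regions$type == "deletion", ]
  expect_equal(amp1$marker_start, del2$marker_start)
  expect_equal(amp1$marker_end, del2$marker_end)
  expect_equal(amp1$g_score, del2$g_score)
})

test_that("regions are disjoint maximal runs and shrink under stricter FDR", {
  spec <- cohort_spec(n_genes = 200, n_cancer = 40, n_normal = 2,
                      frac_de = 0.2, effect_size = 0.8, noise_sd = 0.1,
                      consistency = 1, seed = 15)
  cna <- generate_cna_profiles(spec, segment_length = 10, carrier_frac = 0.4)
  r5 <- call_cna_regions(cna$cohort1, cna$marker_map, fdr_target = 0.05,
                         n_permutations = 60, seed = 2)
  r1 <- call_cna_regions(cna$cohort1, cna$marker_map, fdr_target = 0.01,
                         n_permutations = 60, seed = 2)
  for (type in c("amplification", "deletion")) {
    reg <- r5$regions[r5$regions$type == type, ]
    if (nrow(reg) > 1) {
      o <- order(reg$marker_start)
      # disjoint and maximal: no overlap, and no two adjacent runs touch
      expect_true(all(reg$marker_start[o][-1] > reg$marker_end[o][-nrow(reg)]))
    }
  }
  # 1% FDR markers are a subset of 5% FDR markers
  sig_markers <- function(res, col) res$marker_table$marker[res$marker_table[[col]] <= 0.05]
  expect_true(all(r1$marker_table$marker[r1$marker_table$q_amp <= 0.01] %in%
                    sig_markers(r5, "q_amp")))
  expect_true(all(r1$marker_table$marker[r1$marker_table$q_del <= 0.01] %in%
                    sig_markers(r5, "q_del")))
})

test_that("planted segments are recovered with their genes", {
  spec <- cohort_spec(n_genes = 200, n_cancer = 40, n_normal = 2,
                      frac_de = 0.05, effect_size = 0.8, noise_sd = 0.1,
                      consistency = 1, seed = 23)
  cna <- generate_cna_profiles(spec, segment_length = 10, carrier_frac = 0.4)
  res <- call_cna_regions(cna$cohort1, cna$marker_map, fdr_target = 0.05,
                          n_permutations = 100, seed = 4)
  truth <- cna$truth
  for (i in seq_len(nrow(truth))) {
    type <- if (truth$direction_cohort1[i] > 0) "amplification" else "deletion"
    reg <- res$regions[res$regions$type == type, ]
    hit <- reg$marker_start <= truth$marker_start[i] &
      reg$marker_end >= truth$marker_end[i]
    expect_equal(sum(hit), 1)  # one region covering the whole planted segment
    expect_true(all(truth$genes[[i]] %in% reg$genes[hit][[1]]))
  }
})

test_that("null matrices yield few significant markers and uniform-ish p", {
  spec <- cohort_spec(n_genes = 150, n_cancer = 30, n_normal = 2,
                      frac_de = 0, effect_size = 0, noise_sd = 0.1,
                      consistency = 1, seed = 31)
  fracs <- vapply(1:5, function(r) {
    spec$seed <- 31 + r
    cna <- generate_cna_profiles(spec, segment_length = 10)
    res <- call_cna_regions(cna$cohort1, cna$marker_map, fdr_target = 0.05,
                            n_permutations = 40, seed = r)
    mean(res$marker_table$q_amp <= 0.05 | res$marker_table$q_del <= 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.075)  # 1.5 x nominal
  # empirical p-values roughly uniform under the null
  cna <- generate_cna_profiles(spec, segment_length = 10)
  res <- call_cna_regions(cna$cohort1, cna$marker_map, n_permutations = 60, seed = 1)
  # empirical p-values are discrete; jitter-free KS is only indicative, so
  # compare the ecdf at fixed points instead
  pp <- res$marker_table$p_amp
  expect_lt(max(abs(vapply(c(0.2, 0.5, 0.8), function(q) mean(pp <= q) - q,
                           numeric(1)))), 0.15)
})

test_that("SEG files rasterize to markers with half-open coordinates", {
  seg <- data.frame(
    sample = c("s1", "s1", "s2"),
    chrom = c("chr1", "chr1", "chr1"),
    start = c(1, 200001, 1),          # 1-based inclusive on disk
    end = c(200000, 400000, 400000),
    log2ratio = c(0.8, -0.5, 0.3)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(seg, f, sep = "\t", quote = FALSE, row.names = FALSE)
  om <- read_seg_tsv(f, c(s1 = "cancer", s2 = "cancer"), marker_spacing = 1e5)
  expect_equal(dim(om$values), c(4L, 2L))
  expect_equal(unname(om$values[, "s1"]), c(0.8, 0.8, -0.5, -0.5))
  expect_equal(unname(om$values[, "s2"]), c(0.3, 0.3, 0.3, 0.3))
  map <- attr(om, "marker_map")
  expect_equal(map$start[1], 0)       # 0-based half-open internally
  expect_equal(map$end[1], 1e5)
})
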