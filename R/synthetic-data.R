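#' Specification of a simulated two-cohort case-control design
#'
#' One `cohort_spec` describes a pair of independent cancer-vs-normal
#' cohorts measuring the same genes, with a planted set of truly
#' differential genes whose cross-cohort direction agreement is controlled.
#'
#' @param n_genes number of genes/probes/markers.
#' @param n_cancer,n_normal samples per group in each cohort (>= 2).
#' @param frac_de fraction of genes truly differential, in `[0, 1]`.
#' @param effect_size mean log2 shift (or beta shift, for methylation) of a
#'   true differential gene.
#' @param noise_sd within-group standard deviation (> 0).
#' @param consistency probability that a true differential gene has the
#'   same direction in both cohorts.
#' @param seed integer seed; identical specs generate identical data.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 2000, n_cancer = 20, n_normal = 20,
                        frac_de = 0.1, effect_size = 2, noise_sd = 0.5,
                        consistency = 0.95, seed = 1L) {
  if (n_cancer < 2 || n_normal < 2) stop("sample counts must be >= 2")
  if (frac_de < 0 || frac_de > 1) stop("`frac_de` must be in [0, 1]")
  if (consistency < 0 || consistency > 1) stop("`consistency` must be in [0, 1]")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (frac_de > 0 && round(frac_de * n_genes) < 1)
    stop("`frac_de` > 0 but no gene would be planted; increase `frac_de` or `n_genes`")
  structure(list(n_genes = as.integer(n_genes), n_cancer = as.integer(n_cancer),
                 n_normal = as.integer(n_normal), frac_de = frac_de,
                 effect_size = effect_size, noise_sd = noise_sd,
                 consistency = consistency, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Specification of a synthetic candidate-cancer-gene catalog
#'
#' @param n_oncogenes,n_tsgs counts of candidate oncogenes and tumor
#'   suppressor genes.
#' @param frac_stability fraction of TSGs flagged as stability TSGs
#'   (genome-maintenance genes), in `[0, 1]`.
#' @param mutation_rate per-sample probability that a candidate gene
#'   carries a mutation.
#' @return A list of class `catalog_spec`.
#' @export
catalog_spec <- function(n_oncogenes = 20, n_tsgs = 20, frac_stability = 0.3,
                         mutation_rate = 0.3) {
  if (n_oncogenes < 0 || n_tsgs < 0) stop("counts must be >= 0")
  if (frac_stability < 0 || frac_stability > 1) stop("`frac_stability` in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1) stop("`mutation_rate` in [0, 1]")
  structure(list(n_oncogenes = as.integer(n_oncogenes), n_tsgs = as.integer(n_tsgs),
                 frac_stability = frac_stability, mutation_rate = mutation_rate),
            class = "catalog_spec")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))
sample_ids <- function(prefix, n) sprintf("%s_s%03d", prefix, seq_len(n))

# planted truth shared by expression/methylation generators: which genes are
# differential, base direction in cohort 1, and whether cohort 2 agrees
plant_truth <- function(spec) {
  n_de <- round(spec$frac_de * spec$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(spec$n_genes, n_de)) else integer(0)
  dir1 <- sample(c(-1L, 1L), n_de, replace = TRUE)
  agree <- stats::runif(n_de) < spec$consistency
  dir2 <- ifelse(agree, dir1, -dir1)
  tibble::tibble(gene = gene_ids(spec$n_genes)[de_idx],
                 direction_cohort1 = dir1, direction_cohort2 = as.integer(dir2),
                 consistent = agree)
}

one_expression_cohort <- function(spec, truth, dir_col, cohort) {
  n <- spec$n_cancer + spec$n_normal
  vals <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd),
                 spec$n_genes, n,
                 dimnames = list(gene_ids(spec$n_genes),
                                 c(sample_ids(paste0(cohort, "c"), spec$n_cancer),
                                   sample_ids(paste0(cohort, "n"), spec$n_normal))))
  idx <- match(truth$gene, rownames(vals))
  shift <- truth[[dir_col]] * spec$effect_size
  vals[idx, seq_len(spec$n_cancer)] <-
    vals[idx, seq_len(spec$n_cancer), drop = FALSE] + shift
  omics_matrix(vals, rep(c("cancer", "normal"), c(spec$n_cancer, spec$n_normal)),
               "expression")
}

#' Generate a pair of expression cohorts with planted differential genes
#'
#' Two independent cancer-vs-normal cohorts over the same genes. Exactly
#' `round(frac_de * n_genes)` genes carry a `±effect_size` mean shift in
#' cancer on a Gaussian log2-like background (`noise_sd`); each planted
#' gene keeps the same sign in both cohorts with probability `consistency`,
#' flipping independently otherwise.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `cohort1`, `cohort2` ([omics_matrix()]) and `truth`
#'   (tibble: gene, direction_cohort1, direction_cohort2, consistent).
#' @export
generate_expression_pair <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    truth <- plant_truth(spec)
    list(cohort1 = one_expression_cohort(spec, truth, "direction_cohort1", "c1"),
         cohort2 = one_expression_cohort(spec, truth, "direction_cohort2", "c2"),
         truth = truth)
  })
}

# U/M intensities whose beta tracks a target mean: baseline beta ~ 0.3,
# planted probes shifted by ±beta_shift via scaled M at fixed total signal
one_methylation_cohort <- function(spec, truth, dir_col, cohort, beta_shift,
                                   base_beta, total) {
  n <- spec$n_cancer + spec$n_normal
  probes <- gene_ids(spec$n_genes)
  target <- matrix(base_beta, spec$n_genes, n)
  idx <- match(truth$gene, probes)
  target[idx, seq_len(spec$n_cancer)] <-
    target[idx, seq_len(spec$n_cancer), drop = FALSE] +
    truth[[dir_col]] * beta_shift
  target <- target + matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd),
                            spec$n_genes, n)
  target <- pmin(pmax(target, 0), 0.98)
  # beta = M/(U+M+100): with U+M = total fixed, M = beta*(total+100)
  M <- target * (total + 100)
  U <- total - M
  bad <- U < 0
  if (any(bad)) { M[bad] <- total; U[bad] <- 0 }
  dimnames(M) <- dimnames(U) <-
    list(probes, c(sample_ids(paste0(cohort, "c"), spec$n_cancer),
                   sample_ids(paste0(cohort, "n"), spec$n_normal)))
  list(U = U, M = M,
       groups = rep(c("cancer", "normal"), c(spec$n_cancer, spec$n_normal)))
}

#' Generate a pair of methylation cohorts (probe-level U/M intensities)
#'
#' Like [generate_expression_pair()] but on the beta scale: planted probes
#' are shifted by `±effect_size` (interpreted as a beta shift, so values
#' around 0.1-0.3 are sensible) around a baseline beta of `base_beta`, and
#' the shifts are realized through scaled methylated intensities at a fixed
#' per-probe total signal. `noise_sd` is the per-sample beta noise.
#'
#' @param spec a [cohort_spec()]; `effect_size` and `noise_sd` are on the
#'   beta scale here.
#' @param base_beta baseline methylation level.
#' @param total total `U + M` signal per probe.
#' @return A list with `cohort1`, `cohort2` (each a list `U`, `M`, `groups`)
#'   and `truth` as in [generate_expression_pair()].
#' @export
generate_methylation_pair <- function(spec, base_beta = 0.3, total = 4000) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    truth <- plant_truth(spec)
    list(cohort1 = one_methylation_cohort(spec, truth, "direction_cohort1",
                                          "c1", spec$effect_size, base_beta, total),
         cohort2 = one_methylation_cohort(spec, truth, "direction_cohort2",
                                          "c2", spec$effect_size, base_beta, total),
         truth = truth)
  })
}

#' Beta-value matrix from a generated methylation cohort
#'
#' @param cohort one element (`cohort1`/`cohort2`) of
#'   [generate_methylation_pair()]'s result.
#' @return An [omics_matrix()] of modality `"methylation"`.
#' @export
methylation_cohort_beta <- function(cohort) {
  omics_matrix(compute_beta(cohort$U, cohort$M), cohort$groups, "methylation")
}

#' Generate a pair of copy-number cohorts with planted segments
#'
#' Marker-by-sample log2-ratio matrices with background noise centered at 0
#' and planted contiguous amplification/deletion segments, plus a
#' marker-to-gene map (one gene per marker). Each planted segment is
#' altered (by `±effect_size`) in a fraction `carrier_frac` of cancer-cohort
#' samples; `consistency` controls whether cohort 2 plants the same
#' alteration type. `frac_de` sets the fraction of markers covered by
#' segments.
#'
#' @param spec a [cohort_spec()]; `noise_sd` is the marker-level log2 noise
#'   and `effect_size` the segment amplitude.
#' @param segment_length markers per planted segment.
#' @param carrier_frac fraction of samples carrying each planted segment.
#' @return A list with `cohort1`, `cohort2` ([omics_matrix()], all samples
#'   labeled cancer: copy-number calling needs no normals here),
#'   `marker_map` (tibble: marker, gene) and `truth` (tibble: segment id,
#'   marker_start, marker_end 0-based half-open, direction per cohort,
#'   genes).
#' @export
generate_cna_profiles <- function(spec, segment_length = 10, carrier_frac = 0.4) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n_markers <- spec$n_genes
    markers <- sprintf("m%04d", seq_len(n_markers))
    genes <- gene_ids(n_markers)
    marker_map <- tibble::tibble(marker = markers, gene = genes)
    n_segments <- floor(round(spec$frac_de * n_markers) / segment_length)
    # non-overlapping segment starts on a segment_length grid
    slots <- seq(1, n_markers - segment_length + 1, by = segment_length)
    starts <- if (n_segments > 0) sort(sample(slots, n_segments)) else integer(0)
    dir1 <- sample(c(-1L, 1L), n_segments, replace = TRUE)
    agree <- stats::runif(n_segments) < spec$consistency
    dir2 <- as.integer(ifelse(agree, dir1, -dir1))
    truth <- tibble::tibble(
      segment = seq_len(n_segments),
      marker_start = starts - 1L, marker_end = starts + segment_length - 1L,
      direction_cohort1 = dir1, direction_cohort2 = dir2, consistent = agree,
      genes = lapply(seq_len(n_segments),
                     function(i) genes[starts[i]:(starts[i] + segment_length - 1)])
    )
    make_cohort <- function(dir_col, cohort) {
      n <- spec$n_cancer
      vals <- matrix(stats::rnorm(n_markers * n, 0, spec$noise_sd), n_markers, n,
                     dimnames = list(markers, sample_ids(cohort, n)))
      for (i in seq_len(n_segments)) {
        carriers <- sample.int(n, round(carrier_frac * n))
        rows <- starts[i]:(starts[i] + segment_length - 1)
        vals[rows, carriers] <- vals[rows, carriers, drop = FALSE] +
          truth[[dir_col]][i] * spec$effect_size
      }
      omics_matrix(vals, rep("cancer", n), "cna")
    }
    list(cohort1 = make_cohort("direction_cohort1", "c1"),
         cohort2 = make_cohort("direction_cohort2", "c2"),
         marker_map = marker_map, truth = truth)
  })
}

#' Generate a candidate-gene catalog and per-sample mutation classes
#'
#' Assigns oncogene/TSG roles (and stability flags for TSGs) to the first
#' genes of the simulated cohort, then draws a mutation class per
#' (candidate gene, cancer sample): with probability `mutation_rate` the
#' sample is mutated (activating, inactivating or undetermined, equally
#' likely), otherwise wild type. Mutated strata receive class-specific
#' expression shifts in the returned expression matrix: activating
#' mutations shift the gene up, inactivating down, undetermined and
#' wild-type by the configurable `wild_type_shift`.
#'
#' @param cspec a [catalog_spec()].
#' @param expr an expression [omics_matrix()] to overlay mutation-state
#'   shifts on (e.g. one cohort of [generate_expression_pair()]).
#' @param cancer_type label stored in the catalog.
#' @param shift magnitude of the activating (+) and inactivating (-)
#'   expression shifts.
#' @param wild_type_shift shift applied to wild-type/undetermined samples.
#' @param seed integer seed.
#' @return A list with `catalog` (tibble: gene, role, stability,
#'   cancer_types), `mutations` (tibble: sample, gene, mclass), and `expr`
#'   (the input matrix with stratum shifts applied to candidate genes).
#' @export
generate_catalog_and_mutations <- function(cspec, expr, cancer_type = "cancerA",
                                           shift = 2, wild_type_shift = 0,
                                           seed = 1L) {
  stopifnot(inherits(cspec, "catalog_spec"), inherits(expr, "omics_matrix"))
  n_cand <- cspec$n_oncogenes + cspec$n_tsgs
  genes <- rownames(expr$values)
  if (n_cand > length(genes)) stop("more candidates than genes in the matrix")
  withr::with_seed(seed, {
    cand <- genes[seq_len(n_cand)]
    role <- rep(c("oncogene", "TSG"), c(cspec$n_oncogenes, cspec$n_tsgs))
    n_stab <- round(cspec$frac_stability * cspec$n_tsgs)
    stability <- c(rep(FALSE, cspec$n_oncogenes),
                   rep(c(TRUE, FALSE), c(n_stab, cspec$n_tsgs - n_stab)))
    catalog <- tibble::tibble(gene = cand, role = role, stability = stability,
                              cancer_types = cancer_type)
    cancer_samples <- colnames(expr$values)[expr$groups == "cancer"]
    grid <- expand.grid(sample = cancer_samples, gene = cand,
                        stringsAsFactors = FALSE)
    mutated <- stats::runif(nrow(grid)) < cspec$mutation_rate
    mclass <- ifelse(mutated,
                     sample(c("activating", "inactivating", "undetermined"),
                            nrow(grid), replace = TRUE),
                     "wild_type")
    mutations <- tibble::tibble(sample = grid$sample, gene = grid$gene,
                                mclass = mclass)
    vals <- expr$values
    class_shift <- c(activating = shift, inactivating = -shift,
                     undetermined = wild_type_shift, wild_type = wild_type_shift)
    for (g in cand) {
      rows <- mutations[mutations$gene == g, ]
      vals[g, rows$sample] <- vals[g, rows$sample] +
        unname(class_shift[rows$mclass])
    }
    list(catalog = catalog, mutations = mutations,
         expr = omics_matrix(vals, as.character(expr$groups), expr$modality))
  })
}

#' Write a generated scenario (matrices + truth sidecars) to a directory
#'
#' Truth tables are always written alongside the data as TSV sidecars, so
#' downstream recovery tests never have to re-infer the planted signal.
#'
#' @param pair result of one of the `generate_*` functions.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return The directory, invisibly.
#' @export
write_scenario <- function(pair, dir, prefix = "expression") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in c("cohort1", "cohort2")) {
    om <- pair[[k]]
    if (inherits(om, "omics_matrix")) {
      write_omics_tsv(om,
                      file.path(dir, sprintf("%s_%s.tsv", prefix, k)),
                      file.path(dir, sprintf("%s_%s_labels.tsv", prefix, k)))
    }
  }
  truth <- pair$truth
  if (!is.null(truth)) {
    truth_flat <- as.data.frame(truth)
    listcols <- vapply(truth_flat, is.list, logical(1))
    for (lc in names(truth_flat)[listcols])
      truth_flat[[lc]] <- vapply(truth_flat[[lc]], paste, character(1), collapse = ";")
    utils::write.table(truth_flat, file.path(dir, sprintf("%s_truth.tsv", prefix)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
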