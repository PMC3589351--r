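#' Marker-level G-score
#'
#' Simplified GISTIC-style significance score for one marker:
#' `G = f * a`, where `f` is the fraction of samples whose log2 ratio
#' exceeds the noise threshold (for amplification; falls below `-threshold`
#' for deletion) and `a` is the mean amplitude over those samples (negated
#' values for deletions, so G is always >= 0). `G = 0` when no sample
#' exceeds the threshold.
#'
#' @param values per-sample log2 ratios for one marker (vector) or a
#'   marker-by-sample matrix (one G per row).
#' @param type `"amplification"` or `"deletion"`.
#' @param threshold positive log2-ratio noise threshold (GISTIC convention
#'   0.1).
#' @return Numeric G score(s), >= 0.
#' @examples
#' gscore(c(0.8, 0.8, 0.8, 0.8, 0, 0, 0, 0, 0, 0))  # 0.4 * 0.8 = 0.32
#' @export
gscore <- function(values, type = c("amplification", "deletion"), threshold = 0.1) {
  type <- match.arg(type)
  if (threshold <= 0) stop("`threshold` must be > 0")
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  v <- if (type == "deletion") -values else values
  exceed <- v > threshold
  # f * mean(v[exceed]) = sum(v * exceed) / n_samples
  unname(rowSums(v * exceed) / ncol(v))
}

#' Call significant copy-number regions
#'
#' Scores every marker with [gscore()] for amplification and deletion
#' separately, builds a null G distribution by permuting marker values
#' within each sample (preserving each sample's amplitude distribution),
#' converts to empirical p-values (pooled over markers and permutations),
#' applies Benjamini-Hochberg, and reports maximal contiguous runs of
#' markers with `q <= fdr_target` as regions. Genes are attached through
#' `marker_map`; a gene overlapping both an amplification and a deletion
#' region is marked ambiguous and excluded from the per-gene calls.
#'
#' @param om an [omics_matrix()] of modality `"cna"` (markers x samples,
#'   log2 ratios; marker order is genomic order).
#' @param marker_map data frame with columns `marker`, `gene` (a marker may
#'   map to several genes via repeated rows). Optional; without it regions
#'   carry no genes.
#' @param fdr_target BH q cutoff for significant markers.
#' @param n_permutations within-sample permutations for the null.
#' @param threshold log2 noise threshold passed to [gscore()].
#' @param seed integer seed for the permutations.
#' @return A list with `regions` (tibble: type, marker_start, marker_end
#'   0-based half-open, g_score = max marker G inside, q_value = min marker
#'   q, genes), `gene_calls` (tibble of unambiguous per-gene calls:
#'   `gene`, `direction`, `statistic`, `q_value`, `dataset`, `modality`),
#'   `ambiguous_genes`, and `marker_table` (per-marker G, p, q for both
#'   types).
#' @export
call_cna_regions <- function(om, marker_map = NULL, fdr_target = 0.05,
                             n_permutations = 100, threshold = 0.1,
                             seed = 1L, dataset = "d1") {
  stopifnot(inherits(om, "omics_matrix"))
  vals <- om$values
  if (nrow(vals) < 10) stop("need at least 10 markers")
  if (fdr_target <= 0 || fdr_target > 1) stop("`fdr_target` must be in (0, 1]")
  n_mark <- nrow(vals)
  if (1 / (n_mark * n_permutations) > fdr_target / 10)
    warning("few permutations for the requested FDR resolution; ",
            "consider raising `n_permutations`")

  g_amp <- gscore(vals, "amplification", threshold)
  g_del <- gscore(vals, "deletion", threshold)

  null_g <- withr::with_seed(seed, {
    amp <- numeric(0); del <- numeric(0)
    for (b in seq_len(n_permutations)) {
      perm <- apply(vals, 2, sample)
      amp <- c(amp, gscore(perm, "amplification", threshold))
      del <- c(del, gscore(perm, "deletion", threshold))
    }
    list(amplification = sort(amp), deletion = sort(del))
  })

  emp_p <- function(g, null_sorted) {
    n_null <- length(null_sorted)
    n_ge <- n_null - findInterval(g - 1e-12, null_sorted)
    (1 + n_ge) / (1 + n_null)
  }
  p_amp <- emp_p(g_amp, null_g$amplification)
  p_del <- emp_p(g_del, null_g$deletion)
  q_amp <- stats::p.adjust(p_amp, method = "BH")
  q_del <- stats::p.adjust(p_del, method = "BH")

  runs_of <- function(sig) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])  # 1-based inclusive
  }
  markers <- rownames(vals)
  region_tbl <- function(type, q, g) {
    rn <- runs_of(q <= fdr_target)
    if (!nrow(rn)) return(tibble::tibble(
      type = character(), marker_start = integer(), marker_end = integer(),
      g_score = numeric(), q_value = numeric(), genes = list()))
    tibble::tibble(
      type = type,
      marker_start = rn[, "start"] - 1L,        # 0-based half-open
      marker_end = rn[, "end"],
      g_score = vapply(seq_len(nrow(rn)),
                       function(i) max(g[rn[i, 1]:rn[i, 2]]), numeric(1)),
      q_value = vapply(seq_len(nrow(rn)),
                       function(i) min(q[rn[i, 1]:rn[i, 2]]), numeric(1)),
      genes = lapply(seq_len(nrow(rn)), function(i) {
        if (is.null(marker_map)) return(character(0))
        sort(unique(marker_map$gene[marker_map$marker %in%
                                      markers[rn[i, 1]:rn[i, 2]]]))
      })
    )
  }
  regions <- dplyr::bind_rows(
    region_tbl("amplification", q_amp, g_amp),
    region_tbl("deletion", q_del, g_del)
  )

  amp_genes <- sort(unique(unlist(regions$genes[regions$type == "amplification"])))
  del_genes <- sort(unique(unlist(regions$genes[regions$type == "deletion"])))
  ambiguous <- intersect(amp_genes, del_genes)
  gene_q <- function(gene, type) {
    rows <- which(regions$type == type &
                    vapply(regions$genes, function(g) gene %in% g, logical(1)))
    min(regions$q_value[rows])
  }
  gene_g <- function(gene, type) {
    rows <- which(regions$type == type &
                    vapply(regions$genes, function(g) gene %in% g, logical(1)))
    max(regions$g_score[rows])
  }
  keep_amp <- setdiff(amp_genes, ambiguous)
  keep_del <- setdiff(del_genes, ambiguous)
  gene_calls <- dplyr::bind_rows(
    tibble::tibble(gene = keep_amp, direction = 1L,
                   statistic = vapply(keep_amp, gene_g, numeric(1), type = "amplification"),
                   q_value = vapply(keep_amp, gene_q, numeric(1), type = "amplification")),
    tibble::tibble(gene = keep_del, direction = -1L,
                   statistic = vapply(keep_del, gene_g, numeric(1), type = "deletion"),
                   q_value = vapply(keep_del, gene_q, numeric(1), type = "deletion"))
  )
  if (nrow(gene_calls)) {
    gene_calls$dataset <- dataset
    gene_calls$modality <- "cna"
  } else {
    gene_calls <- tibble::tibble(gene = character(), direction = integer(),
                                 statistic = numeric(), q_value = numeric(),
                                 dataset = character(), modality = character())
  }

  marker_table <- tibble::tibble(
    marker = markers,
    g_amp = g_amp, p_amp = p_amp, q_amp = q_amp,
    g_del = g_del, p_del = p_del, q_del = q_del
  )
  list(regions = regions, gene_calls = gene_calls,
       ambiguous_genes = ambiguous, marker_table = marker_table)
}
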