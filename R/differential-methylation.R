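#' Methylation beta-value from probe intensities
#'
#' `beta = M / (U + M + 100)`, where `U` and `M` are the unmethylated and
#' methylated probe intensities. The +100 regularizer keeps the ratio stable
#' for dim probes and bounds beta strictly below 1.
#'
#' @param U,M non-negative intensity vectors/matrices of equal shape.
#' @return beta values in `[0, 1)`.
#' @examples
#' compute_beta(0, 100)    # 0.5
#' compute_beta(300, 600)  # 0.6
#' @export
compute_beta <- function(U, M) {
  if (any(U < 0) || any(M < 0)) stop("intensities must be non-negative")
  M / (U + M + 100)
}

#' Aggregate probe beta-values to genes
#'
#' Probes mapping to the same gene are averaged (mean beta per sample).
#'
#' @param beta probe-by-sample beta matrix (rownames = probe ids).
#' @param probe_map data frame with columns `probe`, `gene`.
#' @return gene-by-sample beta matrix.
#' @export
aggregate_probes <- function(beta, probe_map) {
  gene <- probe_map$gene[match(rownames(beta), probe_map$probe)]
  if (anyNA(gene)) stop("unmapped probe(s): ",
                        paste(utils::head(rownames(beta)[is.na(gene)]), collapse = ", "))
  agg <- rowsum(beta, gene) / as.vector(table(gene)[sort(unique(gene))])
  agg[sort(unique(gene)), , drop = FALSE]
}

#' Call differentially methylated genes
#'
#' Per-gene two-sample t-test of cancer vs normal beta-values with
#' Benjamini-Hochberg correction; a gene is called when its adjusted p-value
#' is at or below `fdr_target`. Direction +1 means hypermethylated in
#' cancer. Genes with zero variance in both groups are excluded with a
#' warning. Pooled-variance Student's t by default; set `var_equal = FALSE`
#' for Welch.
#'
#' @param om an [omics_matrix()] of modality `"methylation"` holding
#'   gene-level beta-values (see [compute_beta()], [aggregate_probes()]).
#' @param fdr_target BH-adjusted p cutoff.
#' @param var_equal pooled-variance t (default) or Welch.
#' @param dataset id recorded in the output.
#' @return A tibble of differential calls (`gene`, `direction`, `statistic`,
#'   `q_value`, `dataset`, `modality`), with the full per-gene table as
#'   attribute `"gene_table"`.
#' @export
call_dm_genes <- function(om, fdr_target = 0.05, var_equal = TRUE, dataset = "d1") {
  stopifnot(inherits(om, "omics_matrix"))
  if (fdr_target <= 0 || fdr_target > 1) stop("`fdr_target` must be in (0, 1]")
  x <- cancer_cols(om); y <- normal_cols(om)
  ts <- row_t_stats(x, y, var_equal = var_equal)
  if (any(ts$degenerate))
    warning(sum(ts$degenerate), " gene(s) with zero variance in both groups excluded")
  q <- rep(NA_real_, length(ts$p))
  q[!ts$degenerate] <- stats::p.adjust(ts$p[!ts$degenerate], method = "BH")
  called <- !ts$degenerate & q <= fdr_target
  genes <- rownames(om$values)
  gene_table <- tibble::tibble(
    gene = genes, effect = unname(ts$effect), t = unname(ts$t),
    p_value = unname(ts$p), q_value = unname(q),
    called = unname(called), degenerate = unname(ts$degenerate)
  )
  calls <- tibble::tibble(
    gene = genes[called],
    direction = as.integer(sign(ts$effect[called])),
    statistic = unname(ts$t[called]),
    q_value = unname(q[called]),
    dataset = dataset,
    modality = "methylation"
  )
  attr(calls, "gene_table") <- gene_table
  calls
}
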