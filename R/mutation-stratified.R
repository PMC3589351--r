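#' Mutation-state-stratified expression test for one gene
#'
#' Splits the cancer samples by the gene's mutation class (activating,
#' inactivating, undetermined, wild type) and tests each stratum's
#' expression against the normal controls with a two-tailed two-sample
#' t-test (pooled variance by default). Cancer samples without an
#' annotation for the gene are excluded, never defaulted to wild type.
#' Strata with fewer than 2 samples are reported but untested. Raw p-values
#' are reported without multiple-testing correction across strata.
#'
#' @param gene gene id (must be a row of `om`).
#' @param om an expression [omics_matrix()] with both cancer and normal
#'   samples.
#' @param annotation tibble with columns `sample`, `gene`, `mclass`
#'   (one class per sample-gene pair).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return A tibble with one row per stratum: `mclass`, `n`, `mean`,
#'   `mean_normal`, `direction` (sign of stratum-minus-normal difference;
#'   0 when the means tie), `p_value` (`NA` when untested), `tested`.
#' @export
stratify_and_test <- function(gene, om, annotation, var_equal = TRUE) {
  stopifnot(inherits(om, "omics_matrix"))
  if (!gene %in% rownames(om$values)) stop("gene not in matrix: ", gene)
  ann <- annotation[annotation$gene == gene, , drop = FALSE]
  if (anyDuplicated(ann$sample)) stop("multiple mutation classes for one sample")
  normals <- om$values[gene, om$groups == "normal"]
  if (length(normals) < 2) stop("need >= 2 normal samples")
  cancer_samples <- colnames(om$values)[om$groups == "cancer"]
  ann <- ann[ann$sample %in% cancer_samples, , drop = FALSE]
  classes <- c("activating", "inactivating", "undetermined", "wild_type")
  rows <- lapply(classes, function(cl) {
    smp <- ann$sample[ann$mclass == cl]
    x <- om$values[gene, smp]
    n <- length(x)
    if (n == 0) return(NULL)  # empty stratum skipped
    if (n < 2) {
      return(tibble::tibble(mclass = cl, n = n, mean = mean(x),
                            mean_normal = mean(normals),
                            direction = as.integer(sign(mean(x) - mean(normals))),
                            p_value = NA_real_, tested = FALSE))
    }
    tt <- stats::t.test(x, normals, var.equal = var_equal)
    tibble::tibble(mclass = cl, n = n, mean = mean(x),
                   mean_normal = mean(normals),
                   direction = as.integer(sign(mean(x) - mean(normals))),
                   p_value = tt$p.value, tested = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "gene") <- gene
  out
}

#' Flag direction reversals across mutation strata
#'
#' A gene shows a reversal when two mutation strata are each significant at
#' `alpha` but in opposite directions — the situation where the bulk
#' cancer-vs-normal direction of the gene misrepresents at least one
#' mutant's behaviour.
#'
#' @param strata result of [stratify_and_test()] (or several row-bound,
#'   with a `gene` column).
#' @param alpha per-stratum significance level.
#' @return A list: `reversal` (logical), `significant` (the significant
#'   strata), and `pairs` (tibble of opposite-direction significant
#'   stratum pairs).
#' @export
reversal_report <- function(strata, alpha = 0.05) {
  sig <- strata[!is.na(strata$p_value) & strata$p_value <= alpha &
                  strata$direction != 0, , drop = FALSE]
  pairs <- tibble::tibble(stratum_up = character(), stratum_down = character())
  ups <- sig$mclass[sig$direction > 0]
  downs <- sig$mclass[sig$direction < 0]
  if (length(ups) && length(downs))
    pairs <- tidyr_cross(ups, downs)
  list(reversal = nrow(pairs) > 0, significant = sig, pairs = pairs)
}

tidyr_cross <- function(ups, downs) {
  g <- expand.grid(stratum_up = ups, stratum_down = downs,
                   stringsAsFactors = FALSE)
  tibble::as_tibble(g)
}
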