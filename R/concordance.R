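#' Binomial test of cross-cohort directional consistency
#'
#' Given `N` genes whose change direction was determined in two independent
#' cohorts, and `m` of them with the same direction in both, the chance of
#' seeing at least `m` agreements if directions agreed at random with
#' probability `p_r` (a fair coin, `p_r = 0.5`, when up and down are
#' exchangeable) is the upper tail
#' \deqn{p = \sum_{k=m}^{N} \binom{N}{k} p_r^k (1-p_r)^{N-k}.}
#'
#' The sum is evaluated without underflow for `N` well beyond 10^4: for
#' `p_r = 0.5` and `N <= 50` the binomial coefficients are summed exactly in
#' double precision (so symmetric cases such as `N = 27, m = 14` return 0.5
#' exactly); otherwise the terms are accumulated in log space with
#' log-sum-exp. Use `log10 = TRUE` to retrieve tails far below the smallest
#' representable double.
#'
#' @param N number of genes compared (non-negative integer).
#' @param m number of direction-consistent genes, `0 <= m <= N`.
#' @param p_r null probability that one gene agrees by chance.
#' @param log10 if `TRUE`, return `log10(p)` instead of `p`.
#' @return The upper-tail probability (or its base-10 log).
#' @examples
#' binomial_consistency_pvalue(23, 23)   # 0.5^23 = 1.19e-7
#' binomial_consistency_pvalue(27, 14)   # 0.5 by symmetry
#' binomial_consistency_pvalue(4253, 4247, log10 = TRUE)
#' @export
binomial_consistency_pvalue <- function(N, m, p_r = 0.5, log10 = FALSE) {
  if (length(N) != 1 || length(m) != 1 || N < 0 || N != round(N) || m != round(m))
    stop("`N` and `m` must be single non-negative integers")
  if (m > N) stop("`m` cannot exceed `N`")
  if (m < 0) stop("`m` must be >= 0")
  if (p_r <= 0 || p_r >= 1) stop("`p_r` must lie in (0, 1)")
  if (m == 0) return(if (log10) 0 else 1)

  if (p_r == 0.5 && N <= 50) {
    # choose() is exact here and the terms are exact multiples of 2^-N,
    # so the sum is exact (e.g. the symmetric odd-N case gives 0.5 exactly)
    p <- sum(choose(N, m:N)) * 2^-N
    return(if (log10) log10(p) else p)
  }
  log_terms <- lchoose(N, m:N) + (m:N) * log(p_r) + (N - (m:N)) * log1p(-p_r)
  mx <- max(log_terms)
  log_p <- mx + log(sum(exp(log_terms - mx)))
  if (log10) log_p / log(10) else exp(min(log_p, 0))
}

new_concordance_report <- function(N, m, variant, modality = NA_character_) {
  rate <- if (N > 0) m / N else NA_real_
  p <- if (N > 0) binomial_consistency_pvalue(N, m) else NA_real_
  log10_p <- if (N > 0) binomial_consistency_pvalue(N, m, log10 = TRUE) else NA_real_
  structure(
    list(N = N, m = m, agreement_rate = rate, p_value = p, log10_p = log10_p,
         variant = variant, modality = modality, empty = N == 0),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<concordance_report> %s: no genes to compare\n", x$variant))
  } else {
    cat(sprintf("<concordance_report> %s [%s]: %.2f%% (%d of %d), binomial p = %s\n",
                x$variant, x$modality, 100 * x$agreement_rate, x$m, x$N,
                format(x$p_value, digits = 3)))
  }
  invisible(x)
}

#' @export
as.data.frame.concordance_report <- function(x, ...) {
  data.frame(variant = x$variant, modality = x$modality, N = x$N, m = x$m,
             agreement_rate = x$agreement_rate, p_value = x$p_value,
             log10_p = x$log10_p, stringsAsFactors = FALSE)
}

check_calls <- function(calls) {
  need <- c("gene", "direction")
  if (!all(need %in% names(calls)))
    stop("differential calls need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(calls$gene))
    stop("one call per gene expected")
  if (!all(calls$direction %in% c(-1, 1)))
    stop("direction must be +1 or -1")
  calls
}

call_modality <- function(callsA, callsB) {
  mods <- unique(c(callsA$modality, callsB$modality))
  mods <- mods[!is.na(mods)]
  if (length(mods) > 1)
    stop("calls come from different modalities: ", paste(mods, collapse = ", "))
  if (length(mods)) mods else NA_character_
}

#' Directional agreement of genes called in both cohorts
#'
#' The headline agreement statistic: among genes called differential in both
#' of two independent cohorts, the fraction whose change direction agrees,
#' with the binomial consistency p-value.
#'
#' @param callsA,callsB differential-call tables (see [call_de_genes()]) with
#'   columns `gene` and `direction`, one row per gene, same modality.
#' @return A `concordance_report` with `N` = genes shared, `m` = agreeing.
#' @export
shared_agreement <- function(callsA, callsB) {
  check_calls(callsA); check_calls(callsB)
  mod <- call_modality(callsA, callsB)
  shared <- intersect(callsA$gene, callsB$gene)
  dirA <- callsA$direction[match(shared, callsA$gene)]
  dirB <- callsB$direction[match(shared, callsB$gene)]
  new_concordance_report(length(shared), sum(dirA == dirB), "shared", mod)
}

#' Directional agreement over the union of calls
#'
#' Genes called in at least one cohort all enter the comparison. A gene
#' called in both cohorts is consistent when the two call directions agree;
#' a gene called in only one cohort is consistent when its call direction
#' matches the sign of its (possibly non-significant) effect in the other
#' cohort. A zero effect in the reference cohort counts as inconsistent.
#'
#' @inheritParams shared_agreement
#' @param statsA,statsB per-gene effect tables for each cohort (columns
#'   `gene`, `effect`, `p_value`; see [dataset_stats()]).
#' @return A `concordance_report` with variant `"union"`.
#' @export
union_agreement <- function(callsA, callsB, statsA, statsB) {
  check_calls(callsA); check_calls(callsB)
  mod <- call_modality(callsA, callsB)
  genes <- union(callsA$gene, callsB$gene)
  dirA <- callsA$direction[match(genes, callsA$gene)]
  dirB <- callsB$direction[match(genes, callsB$gene)]
  effA <- statsA$effect[match(genes, statsA$gene)]
  effB <- statsB$effect[match(genes, statsB$gene)]
  refA <- ifelse(is.na(dirA), sign(effA), dirA)  # direction or fallback sign
  refB <- ifelse(is.na(dirB), sign(effB), dirB)
  consistent <- !is.na(refA) & !is.na(refB) & refA != 0 & refB != 0 & refA == refB
  new_concordance_report(length(genes), sum(consistent), "union", mod)
}

#' Directional agreement against marginally significant genes
#'
#' Restricts the calls of cohort A to genes showing at least marginally
#' significant change (two-sided `p < p_cut`) in cohort B, then scores sign
#' agreement against cohort B's effect direction.
#'
#' @param callsA differential calls from cohort A.
#' @param statsB per-gene statistics for cohort B ([dataset_stats()]).
#' @param p_cut marginal significance cutoff applied to cohort B's p-values.
#' @return A `concordance_report` with variant `"marginal"`.
#' @export
marginal_agreement <- function(callsA, statsB, p_cut = 0.1) {
  check_calls(callsA)
  mod <- call_modality(callsA, callsA)
  pB <- statsB$p_value[match(callsA$gene, statsB$gene)]
  effB <- statsB$effect[match(callsA$gene, statsB$gene)]
  keep <- !is.na(pB) & pB < p_cut
  dirA <- callsA$direction[keep]
  sB <- sign(effB[keep])
  consistent <- sB != 0 & dirA == sB
  new_concordance_report(sum(keep), sum(consistent), "marginal", mod)
}

#' Validate non-overlapping calls against a third cohort
#'
#' Genes called in exactly one of two cohorts are checked against an
#' independent third cohort: among those also called there, the fraction
#' whose direction matches the third cohort's call.
#'
#' @param nonoverlap_calls calls for genes detected in only one of the two
#'   primary cohorts (e.g. `dplyr::anti_join` of the two call sets, or built
#'   with [merge_consistent()] minus the shared genes).
#' @param third_calls differential calls from the third cohort.
#' @return A `concordance_report` with variant `"third_dataset"`.
#' @export
third_dataset_agreement <- function(nonoverlap_calls, third_calls) {
  check_calls(nonoverlap_calls); check_calls(third_calls)
  mod <- call_modality(nonoverlap_calls, third_calls)
  shared <- intersect(nonoverlap_calls$gene, third_calls$gene)
  dirA <- nonoverlap_calls$direction[match(shared, nonoverlap_calls$gene)]
  dirT <- third_calls$direction[match(shared, third_calls$gene)]
  new_concordance_report(length(shared), sum(dirA == dirT), "third_dataset", mod)
}

#' Merge two cohorts' calls, dropping direction conflicts
#'
#' The merged list used downstream: genes called in at least one cohort,
#' minus genes called in both with opposite directions. A gene called in
#' both with the same direction appears once; a gene called in only one
#' cohort keeps that cohort's direction.
#'
#' @inheritParams shared_agreement
#' @return A tibble of calls (one row per gene) with a `datasets` column
#'   noting which cohort(s) contributed.
#' @export
merge_consistent <- function(callsA, callsB) {
  check_calls(callsA); check_calls(callsB)
  genes <- union(callsA$gene, callsB$gene)
  dirA <- callsA$direction[match(genes, callsA$gene)]
  dirB <- callsB$direction[match(genes, callsB$gene)]
  conflict <- !is.na(dirA) & !is.na(dirB) & dirA != dirB
  keep <- !conflict
  mod <- call_modality(callsA, callsB)
  tibble::tibble(
    gene = genes[keep],
    direction = ifelse(is.na(dirA[keep]), dirB[keep], dirA[keep]),
    modality = mod,
    datasets = dplyr::case_when(
      is.na(dirA[keep]) ~ "B",
      is.na(dirB[keep]) ~ "A",
      TRUE ~ "A;B"
    )
  )
}

#' Per-gene two-sample effect and p-value for one cohort
#'
#' Welch t-test of cancer vs normal for every feature; the effect is the
#' cancer-minus-normal mean difference. Used by the union and marginal
#' agreement variants, which need directions and marginal p-values for genes
#' that were not called.
#'
#' @param om an [omics_matrix()].
#' @return A tibble with columns `gene`, `effect`, `t`, `p_value`.
#' @export
dataset_stats <- function(om) {
  stopifnot(inherits(om, "omics_matrix"))
  x <- cancer_cols(om); y <- normal_cols(om)
  ts <- row_t_stats(x, y, var_equal = FALSE)
  tibble::tibble(gene = rownames(om$values), effect = ts$effect,
                 t = ts$t, p_value = ts$p)
}
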