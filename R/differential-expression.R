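#' Configuration for the SAM-style differential expression caller
#'
#' @param s0_strategy how the exchangeability (fudge) constant s0 is chosen:
#'   `"percentile-search"` picks the percentile of the gene-wise standard
#'   errors minimizing the coefficient of variation of the d-statistic
#'   across standard-error bins; `"fixed"` uses `s0_value` as given.
#' @param s0_value fixed s0 (ignored unless `s0_strategy = "fixed"`).
#' @param n_permutations group-label permutations for the null d
#'   distribution (>= 10).
#' @param fdr_target permutation-estimated FDR at which genes are called.
#' @param seed integer seed for the permutation draw.
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(s0_strategy = c("percentile-search", "fixed"),
                       s0_value = NULL, n_permutations = 200,
                       fdr_target = 0.05, seed = 1L) {
  s0_strategy <- match.arg(s0_strategy)
  if (n_permutations < 10) stop("need at least 10 permutations")
  if (fdr_target <= 0 || fdr_target > 1) stop("`fdr_target` must be in (0, 1]")
  if (s0_strategy == "fixed") {
    if (is.null(s0_value) || s0_value < 0) stop("fixed strategy needs s0_value >= 0")
  }
  structure(list(s0_strategy = s0_strategy, s0_value = s0_value,
                 n_permutations = as.integer(n_permutations),
                 fdr_target = fdr_target, seed = as.integer(seed)),
            class = "sam_config")
}

# mean difference and gene-specific pooled standard error per Tusher's
# relative difference: s = sqrt((1/n1 + 1/n2) * (SS1 + SS2)/(n1 + n2 - 2))
sam_components <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss <- rowSums((x - m1)^2) + rowSums((y - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(diff = m1 - m2, s = s)
}

#' SAM relative-difference statistic
#'
#' `d = (mean(cancer) - mean(normal)) / (s + s0)` where `s` is the gene's
#' pooled standard error. Genes with `s + s0 = 0` (no variance and no fudge)
#' get `NA` and are excluded from calling.
#'
#' @param x,y numeric matrices (features x samples) for the two groups, or
#'   numeric vectors for a single gene.
#' @param s0 fudge constant added to the denominator.
#' @return Numeric vector of d statistics.
#' @examples
#' sam_statistic(c(3, 3), c(1, 1), s0 = 1)  # 2
#' @export
sam_statistic <- function(x, y, s0 = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  if (s0 < 0) stop("`s0` must be >= 0")
  if (ncol(x) < 2 || ncol(y) < 2) stop("need >= 2 samples per group")
  cmp <- sam_components(x, y)
  denom <- cmp$s + s0
  d <- cmp$diff / denom
  d[denom == 0] <- NA_real_
  unname(d)
}

#' Choose the SAM fudge constant s0
#'
#' Searches the percentiles (0, 5, ..., 100) of the gene-wise standard
#' errors `s` for the value minimizing the coefficient of variation of the
#' median absolute deviation of `d` across `s`-quantile bins (the standard
#' SAM tuning criterion). Falls back to `median(s)` when the criterion is
#' flat or undefined across the grid.
#'
#' @param diff per-gene mean differences.
#' @param s per-gene pooled standard errors.
#' @param n_bins number of `s`-quantile bins used to assess d dispersion.
#' @return A single s0 value.
#' @export
choose_s0 <- function(diff, s, n_bins = 20) {
  stopifnot(length(diff) == length(s))
  candidates <- unname(stats::quantile(s, seq(0, 1, by = 0.05), type = 7))
  bins <- cut(rank(s, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  cv <- vapply(candidates, function(s0) {
    d <- diff / (s + s0)
    d <- d[is.finite(d)]
    if (!length(d)) return(NA_real_)
    mads <- tapply(diff / (s + s0), bins, function(v) stats::mad(v[is.finite(v)]))
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(NA_real_)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  if (all(!is.finite(cv)) || diff(range(cv[is.finite(cv)])) < 1e-12)
    return(stats::median(s))
  candidates[which.min(cv)]
}

# distinct group-label permutations as a list of cancer-column index sets;
# includes the observed labelling's complement-free draw when sampling
draw_permutations <- function(groups, n_perm, seed) {
  n <- length(groups)
  n1 <- sum(groups == "cancer")
  total <- choose(n, n1)
  if (total <= n_perm) {
    if (total < n_perm)
      warning(sprintf("only %d distinct permutations available (requested %d)",
                      total, n_perm))
    sets <- utils::combn(n, n1, simplify = FALSE)
  } else {
    sets <- withr::with_seed(seed, {
      seen <- new.env(hash = TRUE)
      out <- vector("list", n_perm)
      k <- 0L
      while (k < n_perm) {
        cand <- sort(sample.int(n, n1))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          k <- k + 1L
          out[[k]] <- cand
        }
      }
      out
    })
  }
  sets
}

#' Call differentially expressed genes (SAM-style, permutation FDR)
#'
#' Computes the d-statistic per gene, builds a null d distribution by
#' permuting the cancer/normal labels, and calls all genes with `|d|` at or
#' above the smallest symmetric threshold whose permutation-estimated FDR
#' (median null exceedance count over observed count, true-null proportion
#' fixed at 1) stays at or below `cfg$fdr_target`. Direction is the sign of
#' the cancer-minus-normal mean difference.
#'
#' @param om an [omics_matrix()] of modality `"expression"` (any modality on
#'   a log-like scale works).
#' @param cfg a [sam_config()].
#' @param dataset id recorded in the output.
#' @return A tibble of class-agnostic differential calls: columns `gene`,
#'   `direction` (+1/-1), `statistic` (d), `q_value`, `dataset`, `modality`.
#'   The full per-gene table (including uncalled genes) is attached as
#'   attribute `"gene_table"`, and the chosen s0 as `"s0"`.
#' @export
call_de_genes <- function(om, cfg = sam_config(), dataset = "d1") {
  stopifnot(inherits(om, "omics_matrix"))
  x <- cancer_cols(om); y <- normal_cols(om)
  if (ncol(x) < 2 || ncol(y) < 2) stop("need both groups with >= 2 samples")
  cmp <- sam_components(x, y)
  s0 <- switch(cfg$s0_strategy,
               fixed = cfg$s0_value,
               `percentile-search` = choose_s0(cmp$diff, cmp$s))
  denom <- cmp$s + s0
  d <- cmp$diff / denom
  degenerate <- denom == 0
  d[degenerate] <- NA_real_

  vals <- cbind(x, y)
  groups <- om$groups
  perms <- draw_permutations(groups, cfg$n_permutations, cfg$seed)
  null_abs <- lapply(perms, function(idx) {
    xb <- vals[, idx, drop = FALSE]
    yb <- vals[, -idx, drop = FALSE]
    cmpb <- sam_components(xb, yb)
    db <- cmpb$diff / (cmpb$s + s0)
    sort(abs(db[is.finite(db)]))
  })

  obs <- abs(d[!degenerate & is.finite(d)])
  thresholds <- sort(unique(obs), decreasing = TRUE)
  n_obs_ge <- vapply(thresholds, function(th) sum(obs >= th), integer(1))
  med_null <- vapply(thresholds, function(th) {
    stats::median(vapply(null_abs, function(v) length(v) - findInterval(th - 1e-12, v),
                         numeric(1)))
  }, numeric(1))
  fdr_hat <- pmin(1, med_null / n_obs_ge)
  ok <- fdr_hat <= cfg$fdr_target
  delta <- if (any(ok)) min(thresholds[ok]) else Inf

  # per-gene q: smallest estimated FDR over all thresholds at or below the
  # gene's own |d| (suffix minimum along decreasing thresholds)
  q_at <- rev(cummin(rev(fdr_hat)))
  gene_q <- q_at[match(abs(d), thresholds)]
  gene_q[degenerate | !is.finite(d)] <- NA_real_

  genes <- rownames(om$values)
  called <- !degenerate & is.finite(d) & abs(d) >= delta
  gene_table <- tibble::tibble(
    gene = genes, d = unname(d), s = unname(cmp$s), effect = unname(cmp$diff),
    q_value = unname(gene_q), called = called, degenerate = unname(degenerate)
  )
  calls <- tibble::tibble(
    gene = genes[called],
    direction = as.integer(sign(d[called])),
    statistic = unname(d[called]),
    q_value = unname(gene_q[called]),
    dataset = dataset,
    modality = "expression"
  )
  attr(calls, "gene_table") <- gene_table
  attr(calls, "s0") <- s0
  attr(calls, "delta") <- delta
  calls
}
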