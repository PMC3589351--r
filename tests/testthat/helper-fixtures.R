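# Small in-code fixtures shared across test files.

toy_matrix <- function(values, n_cancer, n_normal, modality = "expression",
                       genes = NULL) {
  m <- matrix(values, ncol = n_cancer + n_normal, byrow = TRUE)
  rownames(m) <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  omics_matrix(m, rep(c("cancer", "normal"), c(n_cancer, n_normal)), modality)
}

toy_calls <- function(genes, directions, dataset = "d1", modality = "expression") {
  tibble::tibble(gene = genes, direction = as.integer(directions),
                 statistic = as.numeric(directions), q_value = 0.01,
                 dataset = dataset, modality = modality)
}

toy_stats <- function(genes, effects, p_values = rep(0.5, length(genes))) {
  tibble::tibble(gene = genes, effect = effects, t = effects, p_value = p_values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent tail oracle: brute-force enumeration of all 2^N equally likely
# agree/disagree assignments via an 8-bit popcount table
enumerate_tail <- function(N, m) {
  pc8 <- vapply(0:255, function(x) sum(bitwAnd(x, 2^(0:7)) > 0), integer(1))
  x <- 0:(2^N - 1)
  heads <- pc8[bitwAnd(x, 255L) + 1L] +
    pc8[bitwAnd(bitwShiftR(x, 8L), 255L) + 1L] +
    pc8[bitwAnd(bitwShiftR(x, 16L), 255L) + 1L]
  mean(heads >= m)
}
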