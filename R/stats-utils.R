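# Row-wise two-sample t statistics, vectorized over features.
# Pooled (Student) or Welch variants; agrees with stats::t.test per row
# (checked in the test suite).
row_t_stats <- function(x, y, var_equal = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  eff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(eff))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- eff / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degenerate <- !is.finite(se) | se == 0
  t[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  list(effect = unname(eff), t = unname(t), p = unname(p), se = unname(se),
       df = unname(df), degenerate = unname(degenerate))
}
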