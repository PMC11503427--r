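# Independent brute-force implementations used only as test oracles.
# Everything here is written from the defining formulas with explicit sums
# and loops, deliberately avoiding the code paths under test.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

oracle_pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), n - 2)
}

# rank-interpolation quantile: h = (n - 1) p + 1 between order statistics
oracle_quantile_linear <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Tukey hinges: medians of the lower/upper halves (median included in both
# halves when n is odd)
oracle_hinges <- function(x) {
  s <- sort(x)
  n <- length(s)
  half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  c(median(s[1:half]), median(s[(n - half + 1):n]))
}

oracle_ecdf_leq <- function(x) vapply(x, function(v) mean(x <= v), 0)

oracle_hazen <- function(x) {
  n <- length(x)
  vapply(x, function(v) (sum(x < v) + (sum(x == v) + 1) / 2 - 0.5) / n, 0)
}

oracle_fence <- function(x, k = 1.5) {
  q1 <- oracle_quantile_linear(x, 0.25)
  q3 <- oracle_quantile_linear(x, 0.75)
  iqr <- q3 - q1
  list(lower = q1 - k * iqr, upper = q3 + k * iqr,
       outlier = x < q1 - k * iqr | x > q3 + k * iqr)
}

oracle_oneway_f <- function(values, groups) {
  g <- split(values, groups)
  grand <- sum(values) / length(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  (ssb / df1) / (ssw / df2)
}

oracle_chisq <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  stat
}
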