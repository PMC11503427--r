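test_that("Pearson correlation matches hand computations and errors usefully", {
  perfect <- pearson_r(1:5, 2 * (1:5) + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-10)
  res <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6)
  expect_equal(res$n, 4)
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance in x")
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance in y")
})

test_that("correlation is affine-invariant and flips sign under negative scaling", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(5 * x + 3, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * x, y)$r, -r0, tolerance = 1e-12)
})

test_that("one-way ANOVA reproduces hand-computed sums of squares and t^2 = F", {
  a <- oneway_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(1:3, each = 3))
  expect_equal(a$table$f, 3)
  expect_equal(c(a$table$df1, a$table$df2), c(2, 6))

  set.seed(13)
  v <- rnorm(24); g <- rep(c("a", "b"), each = 12)
  f <- oneway_anova(v, g)$table$f
  t <- t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(f, unname(t^2), tolerance = 1e-12)
})

test_that("Tukey-Kramer flags only the shifted group and matches the range distribution", {
  set.seed(14)
  va <- scale(rnorm(20), scale = FALSE)   # a and b share a sample mean of 0
  vb <- scale(rnorm(25), scale = FALSE)
  v <- c(va, vb, rnorm(22) + 3)           # unequal n, only c shifted
  g <- rep(c("a", "b", "c"), c(20, 25, 22))
  ph <- tukey_kramer(v, g)
  sig <- ph$p_adj < 0.05
  involves_c <- grepl("c", ph$comparison)
  expect_identical(sig, involves_c)
  # adjusted p agrees with ptukey on the Kramer-standardized difference
  fit <- aov(v ~ factor(g))
  mse <- sum(resid(fit)^2) / df.residual(fit)
  ns <- table(g)
  i <- which(ph$comparison == "b-a")
  q <- abs(ph$diff[i]) / sqrt(mse / 2 * (1 / ns[["a"]] + 1 / ns[["b"]]))
  expect_equal(ph$p_adj[i],
               ptukey(q, nmeans = 3, df = df.residual(fit),
                      lower.tail = FALSE),
               tolerance = 1e-8)
  # null data: all adjusted p near 1
  set.seed(15)
  ph0 <- tukey_kramer(rnorm(60), rep(1:3, each = 20))
  expect_true(all(ph0$p_adj > 0.3))
})

test_that("chi-square independence matches hand computation and guards margins", {
  flat <- chi_square_independence(matrix(c(10, 20, 10, 20), 2))
  expect_equal(flat$statistic, 0)
  res <- chi_square_independence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(rowSums(res$expected), rowSums(res$observed))
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)),
               "margin")
  expect_warning(chi_square_independence(matrix(c(2, 3, 4, 1), 2)),
                 "below 5")
})

test_that("two-way type II ANOVA matches the balanced-design closed form", {
  # balanced 2x3 design: type II = sequential sums of squares
  set.seed(16)
  a <- rep(c("x", "y"), each = 15)
  b <- rep(rep(c("p", "q", "r"), each = 5), 2)
  v <- rnorm(30) + (a == "y") * 2
  res <- twoway_anova(v, a, b)
  seq_tab <- anova(lm(v ~ factor(a) + factor(b)))
  expect_equal(res$table$f, seq_tab$`F value`[1:2], tolerance = 1e-10)
  expect_equal(res$table$p, seq_tab$`Pr(>F)`[1:2], tolerance = 1e-10)
  # injected factor_a effect dominates
  expect_lt(res$table$p[res$table$effect == "factor_a"], 1e-4)
  expect_gt(res$table$p[res$table$effect == "factor_b"], 0.05)
})

test_that("two-way ANOVA drops an inestimable interaction with a warning", {
  a <- rep(c("x", "y"), c(6, 4))
  b <- c(rep(c("p", "q"), 3), rep("p", 4))   # y:q cell empty
  expect_warning(res <- twoway_anova(rnorm(10), a, b, interaction = TRUE),
                 "empty cell")
  expect_setequal(res$table$effect, c("factor_a", "factor_b"))
})

test_that("statistics agree with brute-force oracles on random instances", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- pearson_r(x, y)
    r_o <- oracle_pearson(x, y)
    expect_equal(res$r, r_o, tolerance = 1e-10)
    expect_equal(res$p, oracle_pearson_p(r_o, n), tolerance = 1e-10)

    g <- sample(1:3, n, replace = TRUE)
    if (min(table(factor(g, levels = 1:3))) >= 2) {
      expect_equal(oneway_anova(x, g)$table$f, oracle_oneway_f(x, g),
                   tolerance = 1e-10)
    }

    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(suppressWarnings(chi_square_independence(tab))$statistic,
                 oracle_chisq(tab), tolerance = 1e-10)
  }
})

test_that("the pairs bootstrap is deterministic, clamps perfect correlation, and counts degenerates", {
  b1 <- bootstrap_correlation(1:8, (1:8) * 2 + 3, b = 500, seed = 99)
  expect_equal(b1$point_r, 1)
  expect_equal(c(b1$ci_low, b1$ci_high), c(1, 1), tolerance = 1e-12)
  expect_equal(b1$b_used + b1$n_degenerate, 500)

  set.seed(1); x <- rnorm(25); y <- x + rnorm(25)
  b2 <- bootstrap_correlation(x, y, b = 400, seed = 7)
  b3 <- bootstrap_correlation(x, y, b = 400, seed = 7)
  b4 <- bootstrap_correlation(x, y, b = 400, seed = 8)
  expect_identical(b2[c("replicate_summary", "ci_low", "ci_high")],
                   b3[c("replicate_summary", "ci_low", "ci_high")])
  expect_false(identical(b2$replicate_summary, b4$replicate_summary))
  expect_true(b2$ci_low <= b2$replicate_summary &
              b2$replicate_summary <= b2$ci_high)
  expect_error(bootstrap_correlation(1:5, rep(1, 5)), "zero variance")
})

test_that("bootstrap replicate correlations match direct resample computation", {
  set.seed(21)
  x <- rnorm(12); y <- x + rnorm(12)
  b <- bootstrap_correlation(x, y, b = 50, seed = 31)
  # replay: same RNG stream gives the same index matrix
  set.seed(31)
  idx <- matrix(sample.int(12, 12 * 50, replace = TRUE), nrow = 12)
  r <- vapply(seq_len(50), function(j) cor(x[idx[, j]], y[idx[, j]]), 0)
  expect_equal(b$replicate_summary, mean(r), tolerance = 1e-12)
  expect_equal(c(b$ci_low, b$ci_high),
               unname(quantile(r, c(0.025, 0.975))), tolerance = 1e-12)
})

test_that("stratified correlation reports per period and degrades gracefully", {
  set.seed(18)
  co <- random_cohort(300)
  tt <- compute_tfqi(co)
  # threshold 0, above side: reproduces the unstratified per-period r
  sc <- stratified_correlation(tt, "tfqi", threshold = 0)
  for (p in period_levels()) {
    sel <- tt$period == p
    expect_equal(sc$r[sc$period == p], cor(tt$tfqi[sel], tt$ui_ug_L[sel]),
                 tolerance = 1e-12)
  }
  # a threshold above all UI: every period reported, none estimable
  hi <- stratified_correlation(tt, "tfqi", threshold = max(co$ui_ug_L) + 1)
  expect_equal(nrow(hi), 4)
  expect_false(any(hi$estimable))
  expect_true(all(hi$n == 0))
  # tsh/ft4 variants work straight off a cohort
  expect_s3_class(stratified_correlation(co, "ft4", threshold = 0),
                  "stratified_correlation")
  expect_error(stratified_correlation(co, "tfqi", threshold = 0),
               "compute_tfqi")
})

test_that("OLS fits two points exactly, matches r*sd(y)/sd(x), refuses singletons", {
  fit <- ols_fit(c(0, 1), c(0, 2))
  expect_equal(c(fit$slope, fit$intercept), c(2, 0))
  set.seed(19)
  x <- rnorm(40); y <- 1.5 * x + rnorm(40)
  f2 <- ols_fit(x, y)
  expect_equal(f2$slope, cor(x, y) * sd(y) / sd(x), tolerance = 1e-12)
  single <- ols_fit(1, 2)
  expect_false(single$estimable)
  expect_match(single$note, "too few")
  flat <- ols_fit(rep(2, 5), rnorm(5))
  expect_false(flat$estimable)
})
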