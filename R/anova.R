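# One- and two-way ANOVA, Tukey-Kramer post hoc comparisons, and the
# chi-square test of independence, as used for the period-wise comparisons
# of TSH, fT4, TFQI, UI and anti-TPO positivity.

.check_groups <- function(values, groups, min_per_group = 2) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  g <- droplevels(factor(groups[ok]))
  v <- values[ok]
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < min_per_group))
    stop("group(s) with fewer than ", min_per_group, " observations: ",
         paste(names(sizes)[sizes < min_per_group], collapse = ", "))
  list(v = v, g = g)
}

#' One-way fixed-effects ANOVA
#'
#' @param values numeric response.
#' @param groups grouping labels (e.g. gestational period), coercible to a
#'   factor; each group needs at least 2 observations.
#' @return object of class `anova_result` with a one-row `table`
#'   (`effect`, `df1`, `df2`, `f`, `p`) and `design = "oneway"`.
#' @export
oneway_anova <- function(values, groups) {
  d <- .check_groups(values, groups)
  fit <- aov(d$v ~ d$g)
  s <- summary(fit)[[1]]
  structure(list(design = "oneway",
                 table = data.frame(effect = "group",
                                    df1 = s$Df[1], df2 = s$Df[2],
                                    f = s$`F value`[1], p = s$`Pr(>F)`[1],
                                    stringsAsFactors = FALSE),
                 fit = fit),
            class = "anova_result")
}

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' All pairwise group-mean comparisons after a one-way ANOVA, with
#' studentized-range adjusted p-values; the Kramer form of the comparison
#' standard error accommodates unequal group sizes.
#'
#' @inheritParams oneway_anova
#' @param conf_level family-wise confidence level for the intervals.
#' @return data frame of class `posthoc_result`: one row per pair with
#'   `comparison`, `diff`, `se`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_kramer <- function(values, groups, conf_level = 0.95) {
  d <- .check_groups(values, groups)
  fit <- aov(d$v ~ d$g)
  hsd <- TukeyHSD(fit, conf.level = conf_level)[[1]]
  mse <- sum(resid(fit)^2) / df.residual(fit)
  sizes <- table(d$g)
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  se <- vapply(pairs, function(pr)
    sqrt(mse * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]])), numeric(1))
  out <- data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
                    se = se, lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                    p_adj = hsd[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "conf_level") <- conf_level
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction. Warns (does not fail) when any expected count is below 5.
#'
#' @param table matrix of non-negative integer counts with positive row and
#'   column margins.
#' @return object of class `chisq_result`: list with `statistic`, `df`, `p`,
#'   `observed`, `expected`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count(s) below 5; chi-square approximation may be poor")
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, observed = tab, expected = ct$expected),
            class = "chisq_result")
}

#' Two-way ANOVA with type II sums of squares
#'
#' Main-effects-only by default (the unbalanced design's type II tests);
#' the interaction can be requested and is dropped with a warning when empty
#' cells make it inestimable.
#'
#' @param values numeric response (e.g. urinary iodine).
#' @param factor_a,factor_b factors with at least 2 observed levels each
#'   (e.g. anti-TPO positivity and gestational period).
#' @param interaction include the A:B interaction term?
#' @return object of class `anova_result` with one row per effect and
#'   `design = "twoway"`, `ss_type = "II"`.
#' @export
twoway_anova <- function(values, factor_a, factor_b, interaction = FALSE) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  ok <- is.finite(values) & !is.na(factor_a) & !is.na(factor_b)
  a <- droplevels(factor(factor_a[ok]))
  b <- droplevels(factor(factor_b[ok]))
  v <- values[ok]
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need at least 2 observed levels")
  if (interaction && any(table(a, b) == 0)) {
    warning("empty cell(s): interaction inestimable, reporting main effects")
    interaction <- FALSE
  }
  fit <- if (interaction) lm(v ~ a * b) else lm(v ~ a + b)
  an <- car::Anova(fit, type = 2)
  rows <- rownames(an) != "Residuals"
  eff <- rownames(an)[rows]
  eff <- gsub("^a$", "factor_a", gsub("^b$", "factor_b", eff))
  eff <- gsub("^a:b$", "factor_a:factor_b", eff)
  structure(list(design = "twoway", ss_type = "II",
                 table = data.frame(effect = eff, df1 = an$Df[rows],
                                    df2 = an$Df[!rows],
                                    f = an$`F value`[rows],
                                    p = an$`Pr(>F)`[rows],
                                    stringsAsFactors = FALSE),
                 fit = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s%s\n", x$design,
              if (!is.null(x$ss_type)) paste0(" (type ", x$ss_type, " SS)")
              else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> X2=%.4g df=%d p=%.4g\n", x$statistic, x$df,
              x$p))
  invisible(x)
}
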