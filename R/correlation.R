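# Pearson correlation, UI-threshold-stratified per-period correlation, the
# pairs (case) bootstrap, and per-stratum OLS fits.

#' Pearson correlation with a two-sided t-test
#'
#' Pairwise-complete pairs are used; fewer than 3 complete pairs, or a
#' constant variable, is an error.
#'
#' @param x,y numeric vectors of equal length.
#' @return object of class `correlation_result`: list with `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  if (var(x) == 0) stop("zero variance in x")
  if (var(y) == 0) stop("zero variance in y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = n, p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r=%+.3f n=%d p=%.4g\n", x$r, x$n, x$p))
  invisible(x)
}

#' Per-period correlation within a UI stratum
#'
#' Correlates TFQI (or TSH, or fT4) against urinary iodine separately for
#' each gestational period, restricted to one side of a UI threshold. The
#' above-threshold side is strict (`ui > threshold`, "over" the threshold);
#' the complementary side is `ui <= threshold`. Periods with fewer than
#' `min_n` qualifying pairs, or with a constant variable, are reported as
#' not estimable together with their pair count rather than raised.
#'
#' @param x a `tfqi_table` (required for `var_x = "tfqi"`) or [cohort].
#' @param var_x `"tfqi"`, `"tsh"` or `"ft4"`.
#' @param threshold UI threshold, μg/L (>= 0). `threshold = 0` with
#'   `side = "above_strict"` reproduces the unstratified per-period
#'   correlations (UI is non-negative; only exact zeros drop).
#' @param side `"above_strict"` or `"at_or_below"`.
#' @param min_n smallest stratum for which r is reported.
#' @return data frame of class `stratified_correlation`: one row per period
#'   with `period`, `stratum`, `n`, `r`, `p`, `estimable`.
#' @export
stratified_correlation <- function(x, var_x = c("tfqi", "tsh", "ft4"),
                                   threshold = 250,
                                   side = c("above_strict", "at_or_below"),
                                   min_n = 3) {
  stopifnot(inherits(x, "cohort"), is.numeric(threshold), threshold >= 0)
  var_x <- match.arg(var_x)
  side <- match.arg(side)
  col <- switch(var_x, tfqi = "tfqi", tsh = "tsh_uIU_mL", ft4 = "ft4_ng_dL")
  if (is.null(x[[col]]))
    stop("column '", col, "' absent; run compute_tfqi() first for var_x = 'tfqi'")
  v <- x[[col]]; ui <- x$ui_ug_L
  in_stratum <- if (side == "above_strict") !is.na(ui) & ui > threshold
                else !is.na(ui) & ui <= threshold
  stratum_lab <- if (side == "above_strict") sprintf("ui > %g", threshold)
                 else sprintf("ui <= %g", threshold)
  rows <- lapply(period_levels(), function(p) {
    sel <- x$period == p & in_stratum & is.finite(v) & !is.na(ui)
    n <- sum(sel)
    if (n >= min_n && var(v[sel]) > 0 && var(ui[sel]) > 0) {
      res <- pearson_r(v[sel], ui[sel])
      data.frame(period = p, stratum = stratum_lab, n = n, r = res$r,
                 p = res$p, estimable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(period = p, stratum = stratum_lab, n = n, r = NA_real_,
                 p = NA_real_, estimable = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$period <- factor(out$period, levels = period_levels(), ordered = TRUE)
  attr(out, "var_x") <- var_x
  class(out) <- c("stratified_correlation", "data.frame")
  out
}

#' Pairs bootstrap of the Pearson correlation
#'
#' Resamples whole (x, y) pairs with replacement `b` times, computes the
#' correlation of each replicate, and summarises the replicate distribution
#' with its mean (or median) and the 2.5/97.5 percentile interval.
#' Degenerate replicates (zero variance in either resampled variable) are
#' discarded and counted. Fully reproducible for a fixed `seed`.
#'
#' @param x,y numeric vectors of equal length, at least 3 complete pairs.
#' @param b number of bootstrap iterations (default 1000).
#' @param seed optional RNG seed.
#' @param summary `"mean"` or `"median"` of the replicate correlations.
#' @return object of class `bootstrap_result`: list with `point_r`,
#'   `replicate_summary`, `ci_low`, `ci_high`, `b`, `b_used`,
#'   `n_degenerate`, `n`, `seed`, `summary`.
#' @export
bootstrap_correlation <- function(x, y, b = 1000, seed = NULL,
                                  summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(length(x) == length(y), b >= 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  if (var(x) == 0) stop("zero variance in x")
  if (var(y) == 0) stop("zero variance in y")
  if (!is.null(seed)) set.seed(seed)
  point_r <- cor(x, y)

  # vectorised over replicates: one n x b index matrix, column-wise moments
  idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n, ncol = b)
  xc <- x - mean(x); yc <- y - mean(y)     # centred for numerical stability
  X <- matrix(xc[idx], n, b); Y <- matrix(yc[idx], n, b)
  mx <- colMeans(X); my <- colMeans(Y)
  sxx <- colMeans(X * X) - mx^2
  syy <- colMeans(Y * Y) - my^2
  sxy <- colMeans(X * Y) - mx * my
  tol_x <- 1e-12 * var(x); tol_y <- 1e-12 * var(y)
  good <- sxx > tol_x & syy > tol_y
  if (!any(good)) stop("all bootstrap replicates degenerate (zero variance)")
  r <- pmin(1, pmax(-1, sxy[good] / sqrt(sxx[good] * syy[good])))
  ci <- quantile(r, c(0.025, 0.975), names = FALSE)
  structure(list(
    point_r = point_r,
    replicate_summary = if (summary == "mean") mean(r) else median(r),
    ci_low = ci[1], ci_high = ci[2],
    b = b, b_used = sum(good), n_degenerate = sum(!good),
    n = n, seed = seed, summary = summary),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap> point r=%+.3f, %s of %d replicates=%+.3f, 95%% CI (%+.3f, %+.3f), n=%d\n",
    x$point_r, x$summary, x$b_used, x$replicate_summary, x$ci_low, x$ci_high,
    x$n))
  if (x$n_degenerate > 0)
    cat(sprintf("  %d degenerate replicate(s) discarded\n", x$n_degenerate))
  invisible(x)
}

#' Ordinary least-squares line
#'
#' Returns a not-estimable result (rather than an error) when there are
#' fewer than 2 complete pairs or the predictor is constant, mirroring how a
#' single above-threshold measurement precludes a regression line.
#'
#' @param x,y numeric vectors of equal length.
#' @return object of class `ols_fit`: list with `slope`, `intercept`, `n`,
#'   `estimable`, and `note` when not estimable.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 || var(x) == 0) {
    note <- if (n < 2) sprintf("n = %d: too few points for OLS", n)
            else "constant predictor: slope undefined"
    return(structure(list(slope = NA_real_, intercept = NA_real_, n = n,
                          estimable = FALSE, note = note),
                     class = "ols_fit"))
  }
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), n = n, estimable = TRUE,
                 note = NULL),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  if (x$estimable)
    cat(sprintf("<ols_fit> y = %.4g + %.4g x (n=%d)\n", x$intercept, x$slope,
                x$n))
  else cat(sprintf("<ols_fit> not estimable (%s)\n", x$note))
  invisible(x)
}
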