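# End-to-end orchestration: read (or simulate) -> anti-TPO derivation ->
# UI fence -> TFQI -> summaries -> inferential tests -> stratified and
# bootstrapped correlations -> report.

#' Analysis configuration
#'
#' @param input path to a cohort CSV; `NULL` generates a synthetic cohort
#'   from `specs` + `dep`.
#' @param schema optional column mapping for [read_cohort].
#' @param specs,dep synthetic-generation settings, see [generate_cohort].
#' @param outlier_k,outlier_method,outlier_scope fence settings, see
#'   [filter_ui_outliers].
#' @param tfqi_convention,tfqi_scope TFQI settings, see [compute_tfqi].
#' @param tfqi_before_fence compute the TFQI on the pre-fence cohort instead
#'   of the default post-fence reference (sensitivity switch).
#' @param anti_tpo_cutoff positivity cutoff, U/mL.
#' @param ui_threshold stratification threshold, μg/L (> 0).
#' @param bootstrap_b bootstrap iterations (>= 1).
#' @param seed seed driving both synthetic generation (when `dep$seed` is
#'   unset) and the per-period bootstraps.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, schema = NULL,
                            specs = default_period_specs(),
                            dep = dependence_spec(),
                            outlier_k = 1.5,
                            outlier_method = "linear_interpolation",
                            outlier_scope = "pooled",
                            tfqi_convention = "ecdf_leq",
                            tfqi_scope = "pooled",
                            tfqi_before_fence = FALSE,
                            anti_tpo_cutoff = 34,
                            ui_threshold = 250,
                            bootstrap_b = 1000,
                            seed = NULL) {
  stopifnot(ui_threshold > 0, bootstrap_b >= 1)
  structure(list(input = input, schema = schema, specs = specs, dep = dep,
                 outlier_k = outlier_k, outlier_method = outlier_method,
                 outlier_scope = outlier_scope,
                 tfqi_convention = tfqi_convention, tfqi_scope = tfqi_scope,
                 tfqi_before_fence = tfqi_before_fence,
                 anti_tpo_cutoff = anti_tpo_cutoff,
                 ui_threshold = ui_threshold, bootstrap_b = bootstrap_b,
                 seed = seed),
            class = "analysis_config")
}

.period_summary <- function(tt) {
  msd <- function(v) c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  rows <- lapply(period_levels(), function(p) {
    d <- tt[tt$period == p, , drop = FALSE]
    tsh <- msd(d$tsh_uIU_mL); ft4 <- msd(d$ft4_ng_dL)
    ui <- msd(d$ui_ug_L); tfqi <- msd(d$tfqi)
    data.frame(period = p, n = nrow(d),
               tsh_mean = tsh["mean"], tsh_sd = tsh["sd"],
               ft4_ngdl_mean = ft4["mean"], ft4_ngdl_sd = ft4["sd"],
               ft4_pmol_mean = ft4_ngdl_to_pmol(ft4[["mean"]]),
               ft4_pmol_sd = ft4_ngdl_to_pmol(ft4[["sd"]]),
               anti_tpo_pos_pct = 100 * mean(d$anti_tpo_pos, na.rm = TRUE),
               tfqi_mean = tfqi["mean"], tfqi_sd = tfqi["sd"],
               ui_mean = ui["mean"], ui_sd = ui["sd"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read or simulate the cohort; derive anti-TPO
#' positivity; fence UI outliers; compute the TFQI (on the post-fence sample
#' by default); per-period summary table; iodine-status proportions; one-way
#' ANOVA with Tukey-Kramer post hoc for TSH, fT4, TFQI and UI versus period;
#' chi-square for anti-TPO positivity by period; type-II two-way ANOVA for
#' UI by positivity and period; per-period correlations of TFQI/TSH/fT4 with
#' UI on both sides of the threshold, with OLS lines; pairs bootstrap of the
#' above-threshold TFQI-UI correlation per period.
#'
#' @param config an [analysis_config].
#' @return object of class `study_report`.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  dat <- if (!is.null(config$input)) {
    read_cohort(config$input, config$schema)
  } else {
    dep <- config$dep
    if (is.null(dep$seed)) dep$seed <- config$seed
    generate_cohort(config$specs, dep)
  }
  dat <- derive_anti_tpo_positivity(dat, config$anti_tpo_cutoff)
  fence <- filter_ui_outliers(dat, k = config$outlier_k,
                              scope = config$outlier_scope,
                              method = config$outlier_method)
  base <- if (config$tfqi_before_fence) dat else fence$retained
  tt_all <- compute_tfqi(base, config$tfqi_convention, config$tfqi_scope)
  tt <- if (config$tfqi_before_fence) {
    keep <- tt_all$sample_id %in% fence$retained$sample_id
    structure(as.data.frame(tt_all)[keep, , drop = FALSE],
              class = class(tt_all), provenance = attr(tt_all, "provenance"),
              convention = attr(tt_all, "convention"),
              reference_scope = attr(tt_all, "reference_scope"))
  } else tt_all

  summary_tab <- .period_summary(tt)
  iodine <- ui_proportions(tt)

  anova_tabs <- list()
  posthoc_tabs <- list()
  for (v in c("tsh", "ft4", "tfqi", "ui")) {
    col <- switch(v, tsh = "tsh_uIU_mL", ft4 = "ft4_ng_dL", tfqi = "tfqi",
                  ui = "ui_ug_L")
    a <- oneway_anova(tt[[col]], tt$period)
    anova_tabs[[v]] <- cbind(variable = v, a$table)
    ph <- tukey_kramer(tt[[col]], tt$period)
    posthoc_tabs[[v]] <- cbind(variable = v, as.data.frame(ph))
  }
  anova_tab <- do.call(rbind, anova_tabs)
  posthoc_tab <- do.call(rbind, posthoc_tabs)
  rownames(anova_tab) <- rownames(posthoc_tab) <- NULL

  chisq <- chi_square_independence(table(tt$anti_tpo_pos, tt$period))
  twoway <- twoway_anova(tt$ui_ug_L, tt$anti_tpo_pos, tt$period)

  corr <- do.call(rbind, lapply(c("tfqi", "tsh", "ft4"), function(v) {
    rbind(
      cbind(var_x = v, stratified_correlation(tt, v, config$ui_threshold,
                                              "at_or_below")),
      cbind(var_x = v, stratified_correlation(tt, v, config$ui_threshold,
                                              "above_strict")))
  }))
  rownames(corr) <- NULL

  ols <- do.call(rbind, lapply(period_levels(), function(p) {
    do.call(rbind, lapply(c("at_or_below", "above_strict"), function(side) {
      sel <- tt$period == p & !is.na(tt$ui_ug_L) &
        (if (side == "above_strict") tt$ui_ug_L > config$ui_threshold
         else tt$ui_ug_L <= config$ui_threshold)
      fit <- ols_fit(tt$ui_ug_L[sel], tt$tfqi[sel])
      data.frame(period = p, side = side, n = fit$n, slope = fit$slope,
                 intercept = fit$intercept, estimable = fit$estimable,
                 stringsAsFactors = FALSE)
    }))
  }))

  boot <- do.call(rbind, lapply(seq_along(period_levels()), function(i) {
    p <- period_levels()[i]
    sel <- tt$period == p & !is.na(tt$ui_ug_L) &
      tt$ui_ug_L > config$ui_threshold & is.finite(tt$tfqi)
    n <- sum(sel)
    if (n >= 3 && var(tt$tfqi[sel]) > 0 && var(tt$ui_ug_L[sel]) > 0) {
      seed_i <- if (is.null(config$seed)) NULL else config$seed + 1000L + i
      b <- bootstrap_correlation(tt$tfqi[sel], tt$ui_ug_L[sel],
                                 b = config$bootstrap_b, seed = seed_i)
      data.frame(period = p, n = n, point_r = b$point_r,
                 replicate_mean = b$replicate_summary, ci_low = b$ci_low,
                 ci_high = b$ci_high, b = b$b, n_degenerate = b$n_degenerate,
                 estimable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(period = p, n = n, point_r = NA_real_,
                 replicate_mean = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, b = config$bootstrap_b,
                 n_degenerate = NA_integer_, estimable = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))

  structure(list(config = config, cohort = dat, fence = fence,
                 tfqi_table = tt, summary = summary_tab, iodine = iodine,
                 anova = anova_tab, posthoc = posthoc_tab, chisq = chisq,
                 twoway = twoway, correlations = corr, ols = ols,
                 bootstrap = boot,
                 n_input = nrow(dat), n_removed = nrow(fence$removed),
                 n_retained = nrow(fence$retained)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Study report ==\n")
  cat(sprintf("Samples: %d in, %d removed by UI fence, %d analysed\n",
              x$n_input, x$n_removed, x$n_retained))
  cat("\nPer-period summary (mean +/- SD):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf(
      "  %-2s n=%4d  TSH %.2f+/-%.2f  fT4 %.2f+/-%.2f ng/dL (%.2f pmol/L)  anti-TPO %.0f%%  TFQI %+.3f+/-%.3f  UI %.0f+/-%.0f\n",
      s$period[i], s$n[i], s$tsh_mean[i], s$tsh_sd[i], s$ft4_ngdl_mean[i],
      s$ft4_ngdl_sd[i], s$ft4_pmol_mean[i], s$anti_tpo_pos_pct[i],
      s$tfqi_mean[i], s$tfqi_sd[i], s$ui_mean[i], s$ui_sd[i]))
  cat(sprintf("\nIodine status: %.0f%% < 150, %.0f%% < 100, %.0f%% optimal (150-250)\n",
              100 * x$iodine$below_150, 100 * x$iodine$below_100,
              100 * x$iodine$proportions[["optimal_150_250"]]))
  cat(sprintf("\nanti-TPO positivity x period: chi-square p = %.3f\n",
              x$chisq$p))
  cat("\nOne-way ANOVA vs period:\n")
  a <- x$anova
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-5s F(%d,%d) = %.2f, p = %.4g\n", a$variable[i],
                a$df1[i], a$df2[i], a$f[i], a$p[i]))
  cat(sprintf("\nTFQI vs UI above %g ug/L:\n", x$config$ui_threshold))
  cc <- x$correlations
  cc <- cc[cc$var_x == "tfqi" & grepl(">", cc$stratum), ]
  for (i in seq_len(nrow(cc))) {
    if (cc$estimable[i])
      cat(sprintf("  %-2s r = %+.3f (n = %d, p = %.3f)\n", cc$period[i],
                  cc$r[i], cc$n[i], cc$p[i]))
    else
      cat(sprintf("  %-2s not estimable (n = %d)\n", cc$period[i], cc$n[i]))
  }
  bb <- x$bootstrap[x$bootstrap$estimable, , drop = FALSE]
  if (nrow(bb)) {
    cat("\nBootstrap (pairs, above threshold):\n")
    for (i in seq_len(nrow(bb)))
      cat(sprintf("  %-2s r = %+.3f, 95%% CI (%+.3f, %+.3f), n = %d, b = %d\n",
                  bb$period[i], bb$replicate_mean[i], bb$ci_low[i],
                  bb$ci_high[i], bb$n[i], bb$b[i]))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV files (full precision) for the summary table, iodine proportions,
#' tests, correlations, OLS fits, bootstrap results and removed outlier
#' rows, plus a human-readable `report.txt`.
#'
#' @param report a [run_analysis] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, na = "")
    p
  }
  paths <- c(
    out(report$summary, "summary.csv"),
    out(data.frame(category = c(names(report$iodine$proportions),
                                "below_100", "below_150"),
                   proportion = c(report$iodine$proportions,
                                  report$iodine$below_100,
                                  report$iodine$below_150)),
        "iodine.csv"),
    out(report$anova, "anova.csv"),
    out(report$posthoc, "posthoc.csv"),
    out(data.frame(statistic = report$chisq$statistic, df = report$chisq$df,
                   p = report$chisq$p), "chisq.csv"),
    out(cbind(design = "twoway_typeII", report$twoway$table), "twoway.csv"),
    out(report$correlations, "correlations.csv"),
    out(report$ols, "ols.csv"),
    out(report$bootstrap, "bootstrap.csv"),
    out(as.data.frame(report$fence$removed), "removed_outliers.csv"))
  txt <- file.path(dir, "report.txt")
  writeLines(c(capture.output(print(report)), "",
               "Provenance:", paste(" -", provenance(report$tfqi_table))),
             txt)
  invisible(c(paths, txt))
}
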