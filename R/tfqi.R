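# Thyroid Feedback Quantile-based Index. Per measurement,
#   TFQI = cdf(fT4) - (1 - cdf(TSH)),
# with both cumulative distribution functions taken over a reference sample.
# Positive values indicate reduced central (pituitary) sensitivity to
# circulating free thyroxine; negative values indicate increased sensitivity.

#' Empirical cumulative distribution values
#'
#' Evaluates each value's empirical CDF within the vector itself. Under
#' `ecdf_leq` the CDF of x is the proportion of values at or below x, so the
#' maximum maps to exactly 1. Under `hazen` the plotting position
#' (midrank - 0.5) / n is used, so all values lie strictly inside (0, 1) and,
#' absent ties, the values average exactly 0.5. Tied inputs always share a
#' CDF value.
#'
#' @param values numeric vector of finite values.
#' @param convention `"ecdf_leq"` or `"hazen"`.
#' @return numeric vector of probabilities, one per input value.
#' @export
empirical_cdf <- function(values, convention = c("ecdf_leq", "hazen")) {
  convention <- match.arg(convention)
  if (length(values) == 0) stop("empty input")
  if (!all(is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (convention == "ecdf_leq") {
    rank(values, ties.method = "max") / n
  } else {
    (rank(values, ties.method = "average") - 0.5) / n
  }
}

# evaluate the CDF of new points against a frozen reference sample
.cdf_against <- function(reference, x, convention) {
  n <- length(reference)
  sr <- sort(reference)
  n_le <- findInterval(x, sr)                    # count <= x
  if (convention == "ecdf_leq") {
    n_le / n
  } else {
    n_lt <- findInterval(x, sr, left.open = TRUE) # count < x
    (n_lt + (n_le - n_lt) / 2) / n
  }
}

#' Compute the TFQI for every sample in a cohort
#'
#' CDF values of fT4 and TSH are taken over a reference set: by default all
#' rows of the cohort with both measurements present, pooled across periods
#' (the index is one joint ranking of the whole sample); `per_period`
#' re-ranks within each gestational period as a sensitivity analysis. Rows
#' missing TSH or fT4 get `NA` and do not enter the reference.
#'
#' @param x a [cohort].
#' @param convention CDF convention, see [empirical_cdf].
#' @param reference_scope `"pooled"` or `"per_period"`.
#' @return a `tfqi_table`: the cohort with columns `cdf_ft4`, `cdf_tsh` and
#'   `tfqi` appended.
#' @export
compute_tfqi <- function(x, convention = c("ecdf_leq", "hazen"),
                         reference_scope = c("pooled", "per_period")) {
  stopifnot(inherits(x, "cohort"))
  convention <- match.arg(convention)
  reference_scope <- match.arg(reference_scope)
  ok <- is.finite(x$tsh_uIU_mL) & is.finite(x$ft4_ng_dL)
  if (!any(ok)) stop("empty reference set: no rows with both TSH and fT4")
  cdf_ft4 <- cdf_tsh <- rep(NA_real_, nrow(x))
  groups <- if (reference_scope == "pooled") factor(rep("all", nrow(x)))
            else x$period
  for (g in levels(droplevels(groups[ok]))) {
    sel <- ok & groups == g
    if (!any(sel)) next
    cdf_ft4[sel] <- empirical_cdf(x$ft4_ng_dL[sel], convention)
    cdf_tsh[sel] <- empirical_cdf(x$tsh_uIU_mL[sel], convention)
  }
  out <- as.data.frame(x)
  out$cdf_ft4 <- cdf_ft4
  out$cdf_tsh <- cdf_tsh
  out$tfqi <- cdf_ft4 - (1 - cdf_tsh)
  structure(out, class = c("tfqi_table", "cohort", "data.frame"),
            provenance = c(attr(x, "provenance"),
                           sprintf("TFQI computed (%s, %s reference)",
                                   convention, reference_scope)),
            convention = convention, reference_scope = reference_scope)
}

#' Freeze a TFQI reference distribution
#'
#' Stores the sorted fT4 and TSH reference samples together with the CDF
#' convention, so that new measurements can be scored prospectively against
#' a fixed cohort (e.g. for a nomogram-style lookup).
#'
#' @param x a [cohort] (typically post-fence).
#' @param convention CDF convention, see [empirical_cdf].
#' @return object of class `tfqi_reference`.
#' @export
freeze_tfqi_reference <- function(x, convention = c("ecdf_leq", "hazen")) {
  stopifnot(inherits(x, "cohort"))
  convention <- match.arg(convention)
  ok <- is.finite(x$tsh_uIU_mL) & is.finite(x$ft4_ng_dL)
  if (!any(ok)) stop("empty reference set")
  structure(list(ft4 = sort(x$ft4_ng_dL[ok]), tsh = sort(x$tsh_uIU_mL[ok]),
                 convention = convention),
            class = "tfqi_reference")
}

#' Score new measurements against a frozen reference
#'
#' @param reference a [freeze_tfqi_reference] object.
#' @param tsh,ft4 numeric vectors of equal length.
#' @return data frame with `cdf_ft4`, `cdf_tsh`, `tfqi`.
#' @export
score_tfqi <- function(reference, tsh, ft4) {
  stopifnot(inherits(reference, "tfqi_reference"), length(tsh) == length(ft4))
  cdf_ft4 <- .cdf_against(reference$ft4, ft4, reference$convention)
  cdf_tsh <- .cdf_against(reference$tsh, tsh, reference$convention)
  data.frame(cdf_ft4 = cdf_ft4, cdf_tsh = cdf_tsh,
             tfqi = cdf_ft4 - (1 - cdf_tsh))
}

#' Serialize / restore a frozen TFQI reference
#'
#' The sidecar file is JSON holding the sorted reference values and the
#' convention tag.
#'
#' @param reference a `tfqi_reference`.
#' @param path file location.
#' @return `write_tfqi_reference` returns `path` invisibly;
#'   `read_tfqi_reference` returns the restored `tfqi_reference`.
#' @export
write_tfqi_reference <- function(reference, path) {
  stopifnot(inherits(reference, "tfqi_reference"))
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(unclass(reference), path, digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tfqi_reference
#' @export
read_tfqi_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(ft4 = as.numeric(obj$ft4), tsh = as.numeric(obj$tsh),
                 convention = match.arg(obj$convention,
                                        c("ecdf_leq", "hazen"))),
            class = "tfqi_reference")
}

#' Parametric (Gaussian-CDF) reference for the TFQI
#'
#' A variant of the index that replaces the empirical CDFs with a Gaussian
#' CDF for fT4 and a log-Gaussian CDF for TSH, the standard construction for
#' this index family. This is offered as a sensitivity variant; the primary
#' computation is the empirical one in [compute_tfqi].
#'
#' @param mu_ft4,sigma_ft4 mean and SD of fT4 (ng/dL), `sigma_ft4 > 0`.
#' @param mu_log_tsh,sigma_log_tsh mean and SD of natural-log TSH,
#'   `sigma_log_tsh > 0`.
#' @return object of class `parametric_reference`.
#' @export
parametric_reference <- function(mu_ft4, sigma_ft4, mu_log_tsh,
                                 sigma_log_tsh) {
  stopifnot(sigma_ft4 > 0, sigma_log_tsh > 0)
  structure(list(mu_ft4 = mu_ft4, sigma_ft4 = sigma_ft4,
                 mu_log_tsh = mu_log_tsh, sigma_log_tsh = sigma_log_tsh),
            class = "parametric_reference")
}

#' @rdname parametric_reference
#' @param x a [cohort] from which to estimate the four parameters.
#' @export
fit_parametric_reference <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ok <- is.finite(x$tsh_uIU_mL) & is.finite(x$ft4_ng_dL)
  if (sum(ok) < 2) stop("need at least 2 complete rows")
  parametric_reference(mean(x$ft4_ng_dL[ok]), sd(x$ft4_ng_dL[ok]),
                       mean(log(x$tsh_uIU_mL[ok])), sd(log(x$tsh_uIU_mL[ok])))
}

#' Parametric TFQI
#'
#' `pnorm((ft4 - mu)/sigma) - (1 - pnorm((log(tsh) - mu_log)/sigma_log))`.
#'
#' @param tsh TSH, μIU/mL (> 0).
#' @param ft4 free T4, ng/dL.
#' @param ref a [parametric_reference].
#' @return TFQI values in (-1, 1).
#' @export
parametric_tfqi <- function(tsh, ft4, ref) {
  stopifnot(inherits(ref, "parametric_reference"))
  if (any(!is.na(tsh) & tsh <= 0))
    stop("tsh must be positive (log undefined otherwise)")
  pnorm((ft4 - ref$mu_ft4) / ref$sigma_ft4) -
    (1 - pnorm((log(tsh) - ref$mu_log_tsh) / ref$sigma_log_tsh))
}

#' Convert free T4 from ng/dL to pmol/L
#'
#' Multiplies by 12.871, the thyroxine molar-mass conversion factor.
#'
#' @param x fT4 in ng/dL, non-negative.
#' @return fT4 in pmol/L (full precision; round only at presentation).
#' @export
ft4_ngdl_to_pmol <- function(x) {
  if (any(!is.na(x) & x < 0)) stop("ft4 must be non-negative")
  x * 12.871
}
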