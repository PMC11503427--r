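# Tukey IQR "fence" filtering of urinary-iodine values. The fence is applied
# to UI only, never to TSH/fT4.

#' First and third quartiles
#'
#' @param values numeric vector (NAs dropped).
#' @param method `"linear_interpolation"` interpolates between order
#'   statistics (the common software default); `"tukey_hinges"` uses the
#'   median-of-halves hinges.
#' @return named numeric vector `c(q1 = , q3 = )`.
#' @export
compute_quartiles <- function(values,
                              method = c("linear_interpolation",
                                         "tukey_hinges")) {
  method <- match.arg(method)
  x <- values[is.finite(values)]
  if (length(x) < 1) stop("need at least one finite value")
  q <- if (method == "linear_interpolation") {
    quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  } else {
    fivenum(x)[c(2, 4)]
  }
  c(q1 = q[1], q3 = q[2])
}

#' Tukey fence bounds
#'
#' Bounds are `q1 - k * IQR` and `q3 + k * IQR`; a value is an outlier only
#' when strictly outside them (boundary values are retained).
#'
#' @param values numeric vector, at least 4 finite values.
#' @param k fence multiplier (> 0); 1.5 is the conventional fence.
#' @inheritParams compute_quartiles
#' @return object of class `fence_bounds` with elements `q1`, `q3`, `iqr`,
#'   `k`, `lower`, `upper`, `method`.
#' @export
tukey_fence <- function(values, k = 1.5,
                        method = c("linear_interpolation", "tukey_hinges")) {
  method <- match.arg(method)
  x <- values[is.finite(values)]
  if (length(x) < 4)
    stop("fewer than 4 finite values: quartiles too unstable, no fencing")
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  q <- compute_quartiles(x, method)
  iqr <- unname(q["q3"] - q["q1"])
  margin <- if (iqr == 0) 0 else k * iqr  # guards Inf * 0
  structure(list(q1 = unname(q["q1"]), q3 = unname(q["q3"]), iqr = iqr,
                 k = k, lower = unname(q["q1"]) - margin,
                 upper = unname(q["q3"]) + margin, method = method),
            class = "fence_bounds")
}

#' @export
print.fence_bounds <- function(x, ...) {
  cat(sprintf(
    "<fence_bounds> Q1=%.4g Q3=%.4g IQR=%.4g k=%g -> [%.4g, %.4g] (%s)\n",
    x$q1, x$q3, x$iqr, x$k, x$lower, x$upper, x$method))
  invisible(x)
}

#' Flag values strictly outside a fence
#'
#' @param bounds a [tukey_fence] result.
#' @param values numeric vector; `NA` is never flagged.
#' @return logical vector, `TRUE` for outliers.
#' @export
fence_outliers <- function(bounds, values) {
  stopifnot(inherits(bounds, "fence_bounds"))
  out <- !is.na(values) & (values < bounds$lower | values > bounds$upper)
  out
}

#' Remove urinary-iodine outliers from a cohort
#'
#' Fences the UI values (pooled across periods by default, or per period) and
#' partitions the cohort into retained and removed rows. Rows with missing UI
#' cannot be fenced and are always retained.
#'
#' @param x a [cohort].
#' @param k fence multiplier.
#' @param scope `"pooled"` fits one fence to all UI values; `"per_period"`
#'   fits one per gestational period.
#' @inheritParams compute_quartiles
#' @return object of class `ui_fence`: list with `retained` and `removed`
#'   cohorts and `bounds` (a `fence_bounds`, or a named list of them under
#'   `per_period`).
#' @export
filter_ui_outliers <- function(x, k = 1.5, scope = c("pooled", "per_period"),
                               method = c("linear_interpolation",
                                          "tukey_hinges")) {
  stopifnot(inherits(x, "cohort"))
  scope <- match.arg(scope)
  method <- match.arg(method)
  ui <- x$ui_ug_L
  if (all(is.na(ui))) stop("cohort has no UI values to fence")
  if (scope == "pooled") {
    bounds <- tukey_fence(ui, k, method)
    drop <- fence_outliers(bounds, ui)
  } else {
    bounds <- lapply(split(ui, droplevels(x$period)), tukey_fence, k = k,
                     method = method)
    drop <- rep(FALSE, length(ui))
    for (p in names(bounds)) {
      sel <- x$period == p
      drop[sel] <- fence_outliers(bounds[[p]], ui[sel])
    }
  }
  retained <- .subset_cohort(x, !drop)
  removed <- .subset_cohort(x, drop)
  retained <- .add_provenance(retained, sprintf(
    "UI Tukey fence (k=%g, %s, %s): removed %d of %d rows",
    k, scope, method, sum(drop), length(drop)))
  structure(list(retained = retained, removed = removed, bounds = bounds,
                 k = k, scope = scope, method = method),
            class = "ui_fence")
}

#' @export
print.ui_fence <- function(x, ...) {
  cat(sprintf("<ui_fence> %d retained, %d removed (k=%g, %s)\n",
              nrow(x$retained), nrow(x$removed), x$k, x$scope))
  if (inherits(x$bounds, "fence_bounds")) print(x$bounds)
  invisible(x)
}
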