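# Urinary-iodine status classification against the 100 / 150 / 250 ug/L
# thresholds used for pregnancy. The four categories partition [0, Inf):
# [0,100) deficient, [100,150) below the recommended minimum, [150,250]
# optimal, (250,Inf) above. Both 150 and 250 are classified optimal; "above"
# means strictly over 250.

#' Urinary-iodine category labels
#' @return character vector of the four category tags, in increasing order.
#' @export
ui_categories <- function() {
  c("deficient_lt100", "below_recommended_100_150", "optimal_150_250",
    "above_250")
}

#' Classify urinary-iodine values
#'
#' @param ui numeric vector of UI concentrations, μg/L, non-negative.
#' @return factor with levels [ui_categories()]; `NA` stays `NA`.
#' @export
classify_ui <- function(ui) {
  if (any(!is.na(ui) & ui < 0)) stop("ui must be non-negative")
  lab <- ifelse(is.na(ui), NA_character_,
         ifelse(ui < 100, "deficient_lt100",
         ifelse(ui < 150, "below_recommended_100_150",
         ifelse(ui <= 250, "optimal_150_250", "above_250"))))
  factor(lab, levels = ui_categories())
}

#' Cohort iodine-status proportions
#'
#' Category proportions plus the cumulative shares below 100 and below
#' 150 μg/L, over the rows with an observed UI value.
#'
#' @param x a [cohort] or a numeric vector of UI values.
#' @return object of class `ui_proportions`: list with `n`, `proportions`
#'   (named, summing to 1), `below_100`, `below_150`.
#' @export
ui_proportions <- function(x) {
  ui <- if (inherits(x, "cohort")) x$ui_ug_L else x
  ui <- ui[!is.na(ui)]
  if (length(ui) == 0) stop("no UI values")
  cats <- classify_ui(ui)
  prop <- as.numeric(table(cats)) / length(ui)
  names(prop) <- ui_categories()
  structure(list(n = length(ui), proportions = prop,
                 below_100 = unname(prop["deficient_lt100"]),
                 below_150 = unname(prop["deficient_lt100"] +
                                    prop["below_recommended_100_150"])),
            class = "ui_proportions")
}

#' @export
print.ui_proportions <- function(x, ...) {
  cat(sprintf("<ui_proportions> n=%d\n", x$n))
  for (nm in names(x$proportions))
    cat(sprintf("  %-26s %5.1f%%\n", nm, 100 * x$proportions[[nm]]))
  cat(sprintf("  %-26s %5.1f%%\n", "below 150 (cumulative)",
              100 * x$below_150))
  invisible(x)
}
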